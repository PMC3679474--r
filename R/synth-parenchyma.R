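# Synthetic H&E-like parenchyma phantoms with known airspace ground truth.

#' Parameters for a synthetic parenchyma image
#'
#' The phantom is a Poisson-Voronoi tessellation: airspaces are Voronoi
#' cells, tissue is a band of `septal_thickness` centred on the cell
#' boundaries. Optional dark "pigmented macrophage" blobs are placed fully
#' inside airspaces and small white speckles (area < 500 px) on tissue, the
#' two artefact classes the automated morphometry has to cope with.
#'
#' @param image_width,image_height raster size in pixels (defaults 1600 x
#'   1200, the acquisition size of the study design).
#' @param px_per_micron spatial calibration, default 2.764 px/micron.
#' @param target_cell_diameter mean airspace (Voronoi cell) diameter in
#'   microns; sets the Poisson intensity of cell centres.
#' @param septal_thickness inter-airspace tissue wall thickness in microns.
#' @param macrophage_count number of dark intra-airspace blobs (>= 0).
#' @param macrophage_diameter blob diameter in microns; must not exceed
#'   `target_cell_diameter`.
#' @param speckle_count number of small white components (< 500 px each)
#'   drawn on tissue (>= 0).
#' @param noise_sd standard deviation of additive Gaussian pixel noise on
#'   the `[0, 1]` intensity scale.
#' @param seed RNG seed; identical parameters give bit-identical images.
#' @return an object of class `parenchyma_params`.
#' @export
parenchyma_params <- function(image_width = 1600L, image_height = 1200L,
                              px_per_micron = 2.764,
                              target_cell_diameter = 33,
                              septal_thickness = 5,
                              macrophage_count = 0L,
                              macrophage_diameter = 12,
                              speckle_count = 0L,
                              noise_sd = 0.02,
                              seed = 1L) {
  geom <- c(image_width = image_width, image_height = image_height,
            px_per_micron = px_per_micron,
            target_cell_diameter = target_cell_diameter,
            septal_thickness = septal_thickness,
            macrophage_diameter = macrophage_diameter)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric parameters must be positive")
  if (macrophage_count < 0 || speckle_count < 0)
    stop("counts must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (target_cell_diameter <= septal_thickness)
    stop("target_cell_diameter must exceed septal_thickness")
  if (macrophage_count > 0 && macrophage_diameter > target_cell_diameter)
    stop_lungmorph("lungmorph_blob_too_large",
                   "macrophage_diameter exceeds target_cell_diameter; blob cannot fit inside an airspace")
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 px_per_micron = px_per_micron,
                 target_cell_diameter = target_cell_diameter,
                 septal_thickness = septal_thickness,
                 macrophage_count = as.integer(macrophage_count),
                 macrophage_diameter = macrophage_diameter,
                 speckle_count = as.integer(speckle_count),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "parenchyma_params")
}

#' H&E-like rendering palette
#'
#' RGB triplets (0-1) for the four rendered classes. Configuration, not
#' science: airspace near-white, tissue eosin pink, macrophages a dusty
#' brown-tinted pink darker than tissue, speckles pure white.
#'
#' The macrophage color is deliberately closer (in RGB distance) to
#' tissue pink than tissue pink is to white, so that two-class clustering
#' assigns pigmented macrophages to the tissue class — the mechanism by
#' which intra-airspace macrophage accumulation biases measured L_M
#' downward.
#'
#' @export
parenchyma_palette <- function() {
  list(airspace   = c(0.97, 0.96, 0.97),
       tissue     = c(0.91, 0.62, 0.73),
       macrophage = c(0.68, 0.45, 0.52),
       speckle    = c(1.00, 1.00, 1.00))
}

# offsets (dy, dx) of a filled disk of pixel radius r around a centre
disk_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

#' Generate a synthetic parenchyma image
#'
#' Renders a Poisson-Voronoi airspace/septum phantom (see
#' [parenchyma_params()]) and returns both the calibrated RGB image and its
#' ground truth. The ground-truth mask is recorded *before* macrophage and
#' speckle insertion, so it represents the anatomical airspace an ideal
#' measurement would see; the true mean airspace chord is measured from the
#' mask by exhaustive horizontal run-length scanning, never assumed.
#'
#' @param params a [parenchyma_params()] object.
#' @param palette rendering colors, see [parenchyma_palette()].
#' @return a list with elements `image` (a [calibrated_image()]) and
#'   `truth` (airspace mask, true mean airspace chord in microns, airspace
#'   fraction, seed).
#' @export
generate_parenchyma_image <- function(params, palette = parenchyma_palette()) {
  stopifnot(inherits(params, "parenchyma_params"))
  W <- params$image_width; H <- params$image_height
  ppm <- params$px_per_micron

  withr::with_seed(params$seed, {
    d_px <- params$target_cell_diameter * ppm
    # Poisson intensity so that mean cell area = area of a disk of the
    # target diameter: lambda = 4 / (pi d^2)
    lambda <- 4 / (pi * d_px^2)
    n_cells <- max(2L, rpois(1L, lambda * W * H))
    centers <- cbind(runif(n_cells, 0, W), runif(n_cells, 0, H))
    half_sept <- params$septal_thickness * ppm / 2
    mask <- voronoi_airspace_mask(centers, W, H, half_sept)

    chords <- tryCatch(measure_true_chords(mask, ppm),
                       lungmorph_no_chords = function(e) NULL)

    # class raster: 1 tissue, 2 airspace, 3 macrophage, 4 speckle
    classes <- mask + 1L

    place_disks <- function(n, class_id, r_fun, ok_fun) {
      placed <- 0L
      tries <- 0L
      while (placed < n && tries < 200L * n) {
        tries <- tries + 1L
        r <- r_fun()
        off <- disk_offsets(r)
        y0 <- sample.int(H, 1L); x0 <- sample.int(W, 1L)
        yy <- y0 + off$dy; xx <- x0 + off$dx
        if (any(yy < 1L | yy > H | xx < 1L | xx > W)) next
        idx <- cbind(yy, xx)
        if (!ok_fun(idx, r, y0, x0)) next
        classes[idx] <<- class_id
        placed <- placed + 1L
      }
      placed
    }

    # macrophages: pigment blobs lying entirely inside airspace
    if (params$macrophage_count > 0L) {
      r_mac <- params$macrophage_diameter * ppm / 2
      n_mac <- place_disks(
        params$macrophage_count, 3L,
        r_fun = function() r_mac,
        ok_fun = function(idx, r, y0, x0) all(classes[idx] == 2L)
      )
      if (n_mac < params$macrophage_count)
        warning(sprintf("placed %d of %d macrophage blobs", n_mac,
                        params$macrophage_count))
    }

    # speckles: small white components on tissue, clear of airspace and of
    # each other so each stays an isolated component of area < 500 px
    if (params$speckle_count > 0L) {
      n_spk <- place_disks(
        params$speckle_count, 4L,
        r_fun = function() runif(1L, 2, 11.5),
        ok_fun = function(idx, r, y0, x0) {
          halo <- disk_offsets(r + 1.6)
          yy <- y0 + halo$dy; xx <- x0 + halo$dx
          if (any(yy < 1L | yy > H | xx < 1L | xx > W)) return(FALSE)
          all(classes[cbind(yy, xx)] == 1L)
        }
      )
      if (n_spk < params$speckle_count)
        warning(sprintf("placed %d of %d speckles", n_spk,
                        params$speckle_count))
    }

    pal <- rbind(palette$tissue, palette$airspace, palette$macrophage,
                 palette$speckle)
    img <- render_classes(classes, pal, params$noise_sd)

    list(
      image = calibrated_image(img, ppm),
      truth = list(
        airspace_mask = mask,
        true_mean_airspace_chord = if (is.null(chords)) NA_real_ else chords$mean_um,
        true_airspace_fraction = mean(mask == 1L),
        n_cells = n_cells,
        seed = params$seed
      )
    )
  })
}

#' Measure true airspace chords from a binary mask
#'
#' Exhaustive ground-truth oracle: scans every pixel row; each maximal
#' horizontal run of airspace pixels is one chord. Chords touching the
#' left/right border are included, matching the behaviour of a border-to-
#' border test-line scan.
#'
#' @param mask binary matrix, 1 = airspace.
#' @param px_per_micron spatial calibration (> 0).
#' @return list with `mean_um`, `mean_px`, `n_chords`.
#' @export
measure_true_chords <- function(mask, px_per_micron) {
  if (!is_binary_mask(mask)) stop("`mask` must be a binary matrix")
  if (px_per_micron <= 0) stop("`px_per_micron` must be > 0")
  mask <- as_mask(mask)
  lens <- unlist(lapply(seq_len(nrow(mask)), function(y) {
    r <- rle(mask[y, ])
    r$lengths[r$values == 1L]
  }), use.names = FALSE)
  if (length(lens) == 0L)
    stop_lungmorph("lungmorph_no_chords",
                   "mask contains no airspace runs; mean chord undefined")
  list(mean_um = mean(lens) / px_per_micron,
       mean_px = mean(lens),
       n_chords = length(lens))
}
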