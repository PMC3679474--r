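# Automated mean linear intercept (L_M) morphometry:
# segmentation -> small-component exclusion -> line grid -> transition
# counting -> L_M = (N x l) / sum(I), then per-mouse / per-group rollup.

#' Segment an image into airspace and tissue
#'
#' Two-class K-means on the raw RGB pixel vectors. Initialization is
#' deterministic: the two centroids start at the darkest and the brightest
#' pixel colors (Rec. 601 luminance, first occurrence wins ties), so the
#' same image always yields the same mask. The cluster with the higher
#' mean luminance is labelled airspace.
#'
#' A single-color image leaves both initial centroids identical and the
#' two-plane separation undefined; by default this is signalled as a
#' classed error (`lungmorph_degenerate_image`). With
#' `degenerate = "midgray"` the caller's fallback is applied instead: the
#' whole image is labelled airspace when its color is brighter than
#' mid-gray (luminance 0.5), tissue otherwise.
#'
#' @param image a [calibrated_image()].
#' @param degenerate `"error"` (default) or `"midgray"`.
#' @return integer matrix, 1 = airspace, 0 = tissue.
#' @export
segment_airspace <- function(image, degenerate = c("error", "midgray")) {
  degenerate <- match.arg(degenerate)
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  H <- dim(px)[1L]; W <- dim(px)[2L]
  x <- matrix(px, ncol = 3L)            # n_pix x 3, column-major pixel order
  lum <- as.vector(x %*% LUMA)
  i_dark <- which.min(lum)
  i_bright <- which.max(lum)
  init <- rbind(x[i_dark, ], x[i_bright, ])
  if (all(init[1L, ] == init[2L, ])) {
    if (degenerate == "error")
      stop_lungmorph("lungmorph_degenerate_image",
                     "single-color image: two-class segmentation undefined")
    return(matrix(if (lum[1L] > 0.5) 1L else 0L, H, W))
  }
  km <- kmeans2_lloyd(x, init)
  cl_lum <- c(mean(lum[km$cluster == 0L]), mean(lum[km$cluster == 1L]))
  air_cl <- which.max(cl_lum) - 1L
  matrix(as.integer(km$cluster == air_cl), H, W)
}

#' Remove small airspace components
#'
#' Connected components of the airspace class (8-connectivity) with pixel
#' area strictly below `min_area` are reassigned to tissue; this is the
#' "white spaces of area less than `min_area` px excluded" rule that keeps
#' vessels and stray white pixels out of the intercept count. Read
#' strictly: a component of exactly `min_area` pixels is retained. Tissue
#' pixels never change class, so the operation is idempotent and never
#' increases airspace area.
#'
#' @param mask binary matrix, 1 = airspace.
#' @param min_area minimum retained component area in pixels (default 500).
#' @return filtered binary mask with attribute `min_area_applied`.
#' @export
filter_small_airspaces <- function(mask, min_area = 500) {
  if (!is_binary_mask(mask)) stop("`mask` must be a binary matrix")
  mask <- as_mask(mask)
  lab <- label_components8(mask)
  if (length(lab$areas)) {
    small <- lab$areas < min_area
    if (any(small)) {
      drop <- array(FALSE, dim = dim(mask))
      fg <- lab$labels > 0L
      drop[fg] <- small[lab$labels[fg]]
      mask[drop] <- 0L
    }
  }
  attr(mask, "min_area_applied") <- min_area
  mask
}

#' Build the horizontal test-line grid
#'
#' Lines are full image width, placed at rows `0, spacing, 2*spacing, ...`
#' while the row index stays inside the image. For the study's standard
#' field (1200 rows, 69-px spacing, i.e. 25 microns at 2.764 px/micron)
#' this yields N = 18 lines of l = 1600 px, a total scanned length of
#' 28,800 px.
#'
#' @param height,width image dimensions in pixels.
#' @param spacing_px line spacing in pixels (default 69).
#' @return list with `rows` (1-based row indices), `N`, `l`, `spacing_px`,
#'   `total_length_px`.
#' @export
build_line_grid <- function(height, width, spacing_px = 69) {
  stopifnot(height >= 1, width >= 1, spacing_px >= 1)
  rows0 <- seq.int(0L, height - 1L, by = spacing_px)
  list(rows = rows0 + 1L,
       N = length(rows0),
       l = as.integer(width),
       spacing_px = spacing_px,
       total_length_px = length(rows0) * as.numeric(width))
}

#' Count airspace-to-tissue transitions along the line grid
#'
#' Scans each grid line left to right and counts positions where an
#' airspace pixel is immediately followed by a tissue pixel. Only the
#' airspace-to-tissue direction is counted by default (the literal
#' intercept definition used by the automated method); image borders are
#' never transitions. `direction = "both"` additionally counts
#' tissue-to-airspace crossings.
#'
#' @param mask binary matrix, 1 = airspace.
#' @param grid a [build_line_grid()] result consistent with `mask`.
#' @param direction `"air_to_tissue"` (default) or `"both"`.
#' @param px_per_micron optional calibration used to report the scanned
#'   length in microns.
#' @return list with `N`, `l`, `sum_I`, `total_length_px`,
#'   `total_length_um` (NA when no calibration given).
#' @export
count_transitions <- function(mask, grid,
                              direction = c("air_to_tissue", "both"),
                              px_per_micron = NULL) {
  direction <- match.arg(direction)
  if (!is_binary_mask(mask)) stop("`mask` must be a binary matrix")
  if (max(grid$rows) > nrow(mask) || grid$l != ncol(mask))
    stop("grid and mask are shape-inconsistent")
  mask <- as_mask(mask)
  air <- mask[grid$rows, , drop = FALSE] == 1L
  W <- ncol(air)
  sum_I <- if (W < 2L) 0L else sum(air[, -W, drop = FALSE] & !air[, -1L, drop = FALSE])
  if (direction == "both" && W >= 2L)
    sum_I <- sum_I + sum(!air[, -W, drop = FALSE] & air[, -1L, drop = FALSE])
  list(N = grid$N,
       l = grid$l,
       sum_I = as.integer(sum_I),
       total_length_px = grid$total_length_px,
       total_length_um = if (is.null(px_per_micron)) NA_real_
                         else grid$total_length_px / px_per_micron,
       direction = direction)
}

#' Compute the mean linear intercept
#'
#' \eqn{L_M = (N \times l) / \sum I}, converted from pixels to microns by
#' the calibration. `N` is the number of test lines, `l` their length in
#' pixels and \eqn{\sum I} the total number of airspace-to-tissue
#' transitions.
#'
#' @param counts a [count_transitions()] result.
#' @param px_per_micron pixels per micron (> 0).
#' @return L_M in microns (scalar).
#' @export
compute_mli <- function(counts, px_per_micron) {
  stopifnot(px_per_micron > 0)
  if (counts$sum_I <= 0L)
    stop_lungmorph("lungmorph_no_intercepts",
                   "no airspace-to-tissue intercepts; L_M undefined")
  (counts$N * as.numeric(counts$l) / counts$sum_I) / px_per_micron
}

#' Morphometry configuration
#'
#' @param spacing_px test-line spacing in pixels (default 69 = 25 microns
#'   at 2.764 px/micron).
#' @param min_area_px airspace components smaller than this are excluded
#'   (default 500).
#' @param px_per_micron calibration override; `NULL` uses the image's own.
#' @param count_direction `"air_to_tissue"` (default) or `"both"`.
#' @export
mli_config <- function(spacing_px = 69, min_area_px = 500,
                       px_per_micron = NULL,
                       count_direction = c("air_to_tissue", "both")) {
  count_direction <- match.arg(count_direction)
  stopifnot(spacing_px >= 1, min_area_px >= 0,
            is.null(px_per_micron) || px_per_micron > 0)
  list(spacing_px = spacing_px, min_area_px = min_area_px,
       px_per_micron = px_per_micron, count_direction = count_direction)
}

#' Mean linear intercept for one image
#'
#' Runs the full per-image chain — segmentation, small-component
#' exclusion, line grid, transition counting, L_M — and keeps every
#' intermediate for audit. Single-color images fall back to the mid-gray
#' rule of [segment_airspace()]; an all-airspace or all-tissue outcome has
#' no intercepts and is reported as a failed image rather than a number.
#'
#' @param image a [calibrated_image()].
#' @param config a [mli_config()].
#' @return list with `L_M_um`, `mask_raw`, `mask`, `grid`, `counts`,
#'   `px_per_micron`, and `failure` (NULL, or the stage and condition
#'   message when a stage signalled a degenerate input).
#' @export
mli_for_image <- function(image, config = mli_config()) {
  stopifnot(inherits(image, "calibrated_image"))
  ppm <- config$px_per_micron %||% image$px_per_micron
  out <- list(L_M_um = NA_real_, mask_raw = NULL, mask = NULL, grid = NULL,
              counts = NULL, px_per_micron = ppm, failure = NULL)
  stage <- "segment"
  res <- tryCatch({
    mask_raw <- segment_airspace(image, degenerate = "midgray")
    stage <- "filter"
    mask <- filter_small_airspaces(mask_raw, config$min_area_px)
    stage <- "grid"
    grid <- build_line_grid(nrow(mask), ncol(mask), config$spacing_px)
    stage <- "count"
    counts <- count_transitions(mask, grid, config$count_direction, ppm)
    stage <- "mli"
    lm_um <- compute_mli(counts, ppm)
    list(L_M_um = lm_um, mask_raw = mask_raw, mask = mask, grid = grid,
         counts = counts)
  }, lungmorph_error = function(e) {
    list(failure = list(stage = stage, message = conditionMessage(e)))
  })
  out[names(res)] <- res
  out
}

#' Aggregate per-image L_M to mouse and group level
#'
#' Per-mouse L_M is the unweighted mean over that mouse's images; group
#' mean and SEM are computed over mouse-level values (n = mice,
#' SEM = sd/sqrt(n)), the primary aggregation. An image-level group
#' summary (n = images) is also returned for comparison. Mice with no
#' valid image are excluded with a warning.
#'
#' @param per_image data.frame with columns `animal_id`, `group`, and
#'   `L_M_um` (NA = failed image).
#' @return list with `per_mouse`, `per_group` (mouse-level), and
#'   `per_group_imagewise` data.frames.
#' @export
aggregate_mli <- function(per_image) {
  stopifnot(all(c("animal_id", "group", "L_M_um") %in% names(per_image)))
  ok <- !is.na(per_image$L_M_um)
  dropped <- setdiff(unique(per_image$animal_id),
                     unique(per_image$animal_id[ok]))
  if (length(dropped))
    warning(sprintf("excluding %d mouse/mice with no valid image: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  pi_ok <- per_image[ok, , drop = FALSE]
  per_mouse <- do.call(rbind, lapply(split(pi_ok, pi_ok$animal_id), function(d) {
    data.frame(animal_id = d$animal_id[1L], group = d$group[1L],
               n_images = nrow(d), L_M_um = mean(d$L_M_um),
               stringsAsFactors = FALSE)
  }))
  rownames(per_mouse) <- NULL
  per_group <- group_summary(per_mouse$L_M_um, per_mouse$group)
  per_group_imagewise <- group_summary(pi_ok$L_M_um, pi_ok$group)
  list(per_mouse = per_mouse, per_group = per_group,
       per_group_imagewise = per_group_imagewise)
}
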