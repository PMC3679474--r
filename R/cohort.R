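# Cohort design and the on-disk synthetic study bundle.

COHORT_GROUPS <- data.frame(
  group = c("CD-NS", "CD-CSE", "VDD-NS", "VDD-CSE"),
  diet  = c("CD", "CD", "VDD", "VDD"),
  smoke = c("NS", "CSE", "NS", "CSE"),
  stringsAsFactors = FALSE
)

#' Default per-group generator parameters
#'
#' The ground-truth group effects the synthetic cohort emulates, chosen to
#' reproduce the qualitative structure of a 16-week smoke/vitamin-D mouse
#' study: the combined-insult group (VDD-CSE) has the largest airspaces;
#' smoke-exposed groups carry intra-airspace pigmented-macrophage blobs
#' (which bias measured L_M downward, most visibly in CD-CSE); both
#' smoke-exposed groups have raised TLC/compliance and lowered tissue
#' elastance; expression shifts favor proteolysis in VDD-CSE; pathology
#' prevalences follow the study's tabulated per-group percentages.
#'
#' Each group entry holds `parenchyma` overrides for [parenchyma_params()],
#' `mechanics` truth means (Rn, Iaw, G, H; R, C; A, B, K), `expression`
#' log2 fold-changes per gene relative to baseline Ct, and `pathology`
#' presence prevalences per feature.
#'
#' @export
default_group_params <- function() {
  feats <- c("airway_inflammation", "parenchymal_inflammation",
             "pigmented_macrophages", "pneumocyte_hyperplasia")
  mk <- function(parenchyma, mechanics, expression, pathology) {
    names(pathology) <- feats
    list(parenchyma = parenchyma, mechanics = mechanics,
         expression = expression, pathology = pathology)
  }
  list(
    "CD-NS" = mk(
      parenchyma = list(target_cell_diameter = 39, macrophage_count = 0L),
      mechanics = list(Rn = 0.30, Iaw = 0.005, G = 4.0, H = 22,
                       R = 0.60, C = 0.055,
                       A = 1.05, B = 0.95, K = 0.12),
      expression = c(MMP9 = 0, TIMP1 = 0, A1AT = 0, RPL13a = 0),
      pathology = c(0.44, 0.78, 0.00, 0.22)),
    "CD-CSE" = mk(
      parenchyma = list(target_cell_diameter = 35, macrophage_count = 18L),
      mechanics = list(Rn = 0.32, Iaw = 0.005, G = 3.8, H = 18,
                       R = 0.58, C = 0.064,
                       A = 1.25, B = 1.12, K = 0.13),
      expression = c(MMP9 = 0.5, TIMP1 = -0.1, A1AT = -0.2, RPL13a = 0),
      pathology = c(0.00, 0.67, 0.75, 0.00)),
    "VDD-NS" = mk(
      parenchyma = list(target_cell_diameter = 39.5, macrophage_count = 0L),
      mechanics = list(Rn = 0.30, Iaw = 0.005, G = 4.0, H = 21.5,
                       R = 0.60, C = 0.056,
                       A = 1.08, B = 0.97, K = 0.12),
      expression = c(MMP9 = 0.2, TIMP1 = 0, A1AT = -0.1, RPL13a = 0),
      pathology = c(0.55, 0.73, 0.18, 0.45)),
    "VDD-CSE" = mk(
      parenchyma = list(target_cell_diameter = 44, macrophage_count = 12L),
      mechanics = list(Rn = 0.33, Iaw = 0.005, G = 3.7, H = 16,
                       R = 0.57, C = 0.068,
                       A = 1.32, B = 1.18, K = 0.13),
      expression = c(MMP9 = 1.0, TIMP1 = -0.8, A1AT = -1.0, RPL13a = 0),
      pathology = c(0.36, 0.55, 0.91, 0.18))
  )
}

#' Cohort design
#'
#' The 2x2 factorial layout: diet (CD/VDD) crossed with smoke exposure
#' (NS/CSE), `mice_per_group` animals per group and `images_per_mouse`
#' histology fields per animal. Defaults (11 mice, 10 images) give the
#' 440-image morphometry workload of the reference design.
#'
#' @param mice_per_group animals per group (default 11).
#' @param images_per_mouse histology images per animal (default 10).
#' @param master_seed master RNG seed; every per-animal stream is derived
#'   from it by a fixed counter scheme, so regeneration of one animal is
#'   independent of cohort order.
#' @param group_params per-group generator parameters, see
#'   [default_group_params()].
#' @param image_overrides named list of [parenchyma_params()] overrides
#'   applied to every group (e.g. smaller rasters for quick runs).
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(mice_per_group = 11L, images_per_mouse = 10L,
                          master_seed = 1L,
                          group_params = default_group_params(),
                          image_overrides = list()) {
  stopifnot(mice_per_group >= 1L, images_per_mouse >= 1L)
  if (!setequal(names(group_params), COHORT_GROUPS$group))
    stop("group_params must name exactly the four groups")
  structure(list(groups = COHORT_GROUPS,
                 mice_per_group = as.integer(mice_per_group),
                 images_per_mouse = as.integer(images_per_mouse),
                 master_seed = as.integer(master_seed),
                 group_params = group_params,
                 image_overrides = image_overrides),
            class = "cohort_design")
}

#' Animal roster for a design
#'
#' @param design a [cohort_design()].
#' @return data.frame with `animal_id`, `group`, `diet`, `smoke`,
#'   `animal_index`.
#' @export
cohort_animals <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  rows <- lapply(seq_len(nrow(design$groups)), function(gi) {
    g <- design$groups[gi, ]
    data.frame(
      animal_id = sprintf("%s_%02d", gsub("-", "", g$group),
                          seq_len(design$mice_per_group)),
      group = g$group, diet = g$diet, smoke = g$smoke,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$animal_index <- seq_len(nrow(out))
  out
}

#' Generate a synthetic Ct table
#'
#' Ct(gene, animal) = baseline_ct(gene) - log2fc(gene, group(animal)) +
#' noise; higher expression means fewer cycles. The housekeeping gene's
#' fold-change is fixed at 0 in every group, whatever the group parameters
#' say.
#'
#' @param design a [cohort_design()].
#' @param baseline_ct named baseline Ct per gene; must include the
#'   housekeeping gene.
#' @param ct_noise_sd Ct noise sd in cycles.
#' @param housekeeping housekeeping gene name.
#' @return data.frame with `animal_id`, `group`, `diet`, `smoke`, `gene`,
#'   `ct`.
#' @export
generate_ct_table <- function(design,
                              baseline_ct = c(RPL13a = 18, MMP9 = 26,
                                              TIMP1 = 24, A1AT = 22),
                              ct_noise_sd = 0.4,
                              housekeeping = "RPL13a") {
  stopifnot(inherits(design, "cohort_design"))
  if (!housekeeping %in% names(baseline_ct))
    stop(sprintf("baseline_ct must include housekeeping gene '%s'",
                 housekeeping))
  animals <- cohort_animals(design)
  genes <- names(baseline_ct)
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    fc <- design$group_params[[a$group]]$expression
    fc[housekeeping] <- 0
    withr::with_seed(derive_seed(design$master_seed, a$animal_index, 3L), {
      ct <- unname(baseline_ct[genes]) - unname(fc[genes]) +
        rnorm(length(genes), 0, ct_noise_sd)
    })
    data.frame(animal_id = a$animal_id, group = a$group, diet = a$diet,
               smoke = a$smoke, gene = genes, ct = ct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate synthetic pathology scores
#'
#' Per animal and feature, presence is drawn from the group's configured
#' prevalence; present findings receive a four-tier score in 1..3 heavily
#' weighted toward focal (1), matching the sparse upper tiers such scoring
#' produces in practice.
#'
#' @param design a [cohort_design()].
#' @return data.frame with `animal_id`, `group`, `diet`, `smoke`,
#'   `feature`, `score` (0-3), `present` (0/1).
#' @export
generate_pathology_scores <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  animals <- cohort_animals(design)
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    prev <- design$group_params[[a$group]]$pathology
    withr::with_seed(derive_seed(design$master_seed, a$animal_index, 4L), {
      present <- rbinom(length(prev), 1L, unname(prev))
      score <- ifelse(present == 1L,
                      sample(1:3, length(prev), replace = TRUE,
                             prob = c(0.70, 0.25, 0.05)),
                      0L)
    })
    data.frame(animal_id = a$animal_id, group = a$group, diet = a$diet,
               smoke = a$smoke, feature = names(prev), score = score,
               present = present, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-animal mechanics truth: lognormal between-animal variation around
# the group means (cv on the multiplicative scale). A and B are not
# jittered independently: B and the positive P=0 volume gap (A - B) each
# get their own factor, which preserves the A > B > 0 constraint.
draw_animal_mechanics <- function(mech, seed, cv = 0.08) {
  withr::with_seed(seed, {
    jitter <- function(x) x * exp(rnorm(1L, 0, cv))
    out <- lapply(mech, jitter)
    gap <- jitter(mech$A - mech$B)
    out$A <- out$B + gap
    out
  })
}

#' Generate a synthetic study bundle on disk
#'
#' Writes the complete input set the analysis pipeline consumes:
#' `design.csv`, per-animal parenchyma images under `images/`
#' (`<animal>_img<k>.png`), per-animal mechanics records under
#' `mechanics/` (snapshot time series, impedance spectrum, PV loop),
#' `ct.csv`, `pathology.csv`, a `manifest.yaml` recording the calibration
#' and every derived seed, and `truth_images.csv` /
#' `truth_mechanics.csv` with the synthetic ground truth (for validation
#' only; the pipeline never reads them).
#'
#' A fixed `master_seed` yields a byte-identical bundle across runs.
#'
#' @param design a [cohort_design()].
#' @param dir destination directory (created; must not collide with an
#'   existing non-empty bundle unless `overwrite = TRUE`).
#' @param overwrite allow writing into an existing directory.
#' @param verbose print progress.
#' @return invisibly, the manifest list.
#' @export
generate_cohort <- function(design, dir, overwrite = FALSE, verbose = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  if (dir.exists(dir) && length(dir(dir)) && !overwrite)
    stop("destination exists and is not empty; use overwrite = TRUE")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "mechanics"), showWarnings = FALSE)
  if (!dir.exists(dir)) stop("destination not writable")

  animals <- cohort_animals(design)
  if (anyDuplicated(animals$animal_id))
    stop("duplicate animal identifiers in design")
  ppm <- do.call(parenchyma_params, design$image_overrides)$px_per_micron

  write.csv(animals[, c("animal_id", "group", "diet", "smoke")],
            file.path(dir, "design.csv"), row.names = FALSE)

  truth_img <- list(); truth_mech <- list(); seeds <- list()
  for (i in seq_len(nrow(animals))) {
    a <- animals[i, ]
    gp <- design$group_params[[a$group]]
    if (verbose) message("animal ", a$animal_id)

    # histology images (one derived seed per image)
    for (k in seq_len(design$images_per_mouse)) {
      img_seed <- derive_seed(design$master_seed, a$animal_index, 10L + k)
      p_args <- utils::modifyList(
        utils::modifyList(gp$parenchyma, design$image_overrides),
        list(seed = img_seed))
      params <- do.call(parenchyma_params, p_args)
      gen <- generate_parenchyma_image(params)
      fn <- sprintf("%s_img%02d.png", a$animal_id, k)
      png::writePNG(gen$image$pixels, file.path(dir, "images", fn))
      truth_img[[length(truth_img) + 1L]] <- data.frame(
        image = fn, animal_id = a$animal_id, group = a$group,
        true_mean_airspace_chord_um = gen$truth$true_mean_airspace_chord,
        true_airspace_fraction = gen$truth$true_airspace_fraction,
        seed = img_seed, stringsAsFactors = FALSE)
    }

    # mechanics records
    mech_seed <- derive_seed(design$master_seed, a$animal_index, 1L)
    mech <- draw_animal_mechanics(gp$mechanics, mech_seed)
    rec <- generate_snapshot_record(mech$R, mech$C, P0 = 3, noise_sd = 0.05,
                                    seed = derive_seed(design$master_seed,
                                                       a$animal_index, 5L))
    spec <- generate_impedance(mech$Rn, mech$Iaw, mech$G, mech$H,
                               noise_sd = 0.01,
                               seed = derive_seed(design$master_seed,
                                                  a$animal_index, 6L))
    loop <- generate_pv_loop(mech$A, mech$B, mech$K, noise_sd = 0.005,
                             seed = derive_seed(design$master_seed,
                                                a$animal_index, 7L))
    write.csv(rec, file.path(dir, "mechanics",
                             paste0(a$animal_id, "_snapshot.csv")),
              row.names = FALSE)
    write.csv(spec, file.path(dir, "mechanics",
                              paste0(a$animal_id, "_impedance.csv")),
              row.names = FALSE)
    write.csv(loop, file.path(dir, "mechanics",
                              paste0(a$animal_id, "_pv.csv")),
              row.names = FALSE)
    truth_mech[[length(truth_mech) + 1L]] <- data.frame(
      animal_id = a$animal_id, group = a$group,
      Rn = mech$Rn, Iaw = mech$Iaw, G = mech$G, H = mech$H,
      R = mech$R, C = mech$C, A = mech$A, B = mech$B, K = mech$K,
      stringsAsFactors = FALSE)
    seeds[[a$animal_id]] <- list(mechanics = mech_seed)
  }

  ct <- generate_ct_table(design)
  write.csv(ct, file.path(dir, "ct.csv"), row.names = FALSE)
  pathology <- generate_pathology_scores(design)
  write.csv(pathology, file.path(dir, "pathology.csv"), row.names = FALSE)
  write.csv(do.call(rbind, truth_img), file.path(dir, "truth_images.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, truth_mech), file.path(dir, "truth_mechanics.csv"),
            row.names = FALSE)

  manifest <- list(
    package = "lungmorph",
    kind = "synthetic cohort bundle",
    master_seed = design$master_seed,
    px_per_micron = ppm,
    mice_per_group = design$mice_per_group,
    images_per_mouse = design$images_per_mouse,
    n_animals = nrow(animals),
    n_images = nrow(animals) * design$images_per_mouse,
    seed_scheme = "derive_seed(master, animal_index, substream): (master + 7919*animal + 104729*substream) mod 2147483647; substreams: 1 mechanics truth, 3 ct, 4 pathology, 5 snapshot, 6 impedance, 7 pv, 10+k image k",
    animal_seeds = seeds
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
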