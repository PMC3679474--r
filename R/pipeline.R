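# Orchestration: run every analysis stage over an on-disk bundle.

#' Study-level configuration
#'
#' @param spacing_px,min_area_px,count_direction morphometry settings, see
#'   [mli_config()].
#' @param px_per_micron calibration; `NULL` reads it from the bundle
#'   manifest (falling back to 2.764).
#' @param cst_pressure,tlc_pressure PV evaluation pressures (cmH2O).
#' @param alpha significance level for reporting.
#' @param pairs planned comparison pairs; see
#'   [default_comparison_pairs()].
#' @param m Bonferroni family size (default: number of pairs).
#' @param seed seed recorded with outputs (the analysis itself is
#'   deterministic).
#' @export
study_config <- function(spacing_px = 69, min_area_px = 500,
                         count_direction = "air_to_tissue",
                         px_per_micron = NULL,
                         cst_pressure = 5, tlc_pressure = 30,
                         alpha = 0.05,
                         pairs = default_comparison_pairs(),
                         m = length(pairs),
                         seed = 1L) {
  stopifnot(spacing_px > 0, min_area_px >= 0, cst_pressure > 0,
            tlc_pressure > 0, alpha > 0, alpha < 1, m >= 1)
  list(spacing_px = spacing_px, min_area_px = min_area_px,
       count_direction = count_direction, px_per_micron = px_per_micron,
       cst_pressure = cst_pressure, tlc_pressure = tlc_pressure,
       alpha = alpha, pairs = pairs, m = m, seed = as.integer(seed))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lungmorph config_hash=%s seed=%d", hash, seed), con)
  write.csv(df, con, row.names = FALSE)
}

#' Read a CSV written by [run_study()] (skipping the stamp line)
#' @param path file path.
#' @export
read_stamped_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

log_line <- function(log, fmt, ...) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 sprintf(fmt, ...))
  writeLines(msg, log)
  invisible(msg)
}

#' Validate a study bundle
#'
#' Checks image readability, CSV schemas, and design completeness (every
#' animal appearing in the inputs must be in exactly one group). Findings
#' are returned as a report, never raised.
#'
#' @param input_dir bundle directory.
#' @return data.frame with columns `severity`, `file`, `message`; zero
#'   rows when the bundle is well-formed.
#' @export
validate_inputs <- function(input_dir) {
  findings <- list()
  note <- function(severity, file, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, file = file, message = message,
      stringsAsFactors = FALSE)

  design_path <- file.path(input_dir, "design.csv")
  design <- NULL
  if (!file.exists(design_path)) {
    note("error", "design.csv", "missing design table")
  } else {
    design <- tryCatch(read.csv(design_path, stringsAsFactors = FALSE),
                       error = function(e) NULL)
    if (is.null(design)) {
      note("error", "design.csv", "unreadable design table")
    } else {
      need <- c("animal_id", "group", "diet", "smoke")
      miss <- setdiff(need, names(design))
      if (length(miss))
        note("error", "design.csv",
             paste("missing columns:", paste(miss, collapse = ", ")))
      else if (anyDuplicated(design$animal_id))
        note("error", "design.csv", "duplicate animal_id entries")
    }
  }

  img_dir <- file.path(input_dir, "images")
  if (dir.exists(img_dir)) {
    imgs <- list.files(img_dir, pattern = "\\.png$")
    for (fn in imgs) {
      ok <- tryCatch({ png::readPNG(file.path(img_dir, fn)); TRUE },
                     error = function(e) FALSE)
      if (!ok) note("error", file.path("images", fn), "unreadable PNG")
      if (!is.null(design) && "animal_id" %in% names(design)) {
        aid <- sub("_img\\d+\\.png$", "", fn)
        if (!aid %in% design$animal_id)
          note("error", file.path("images", fn),
               sprintf("animal '%s' absent from design.csv", aid))
      }
    }
  }

  check_table <- function(fname, need) {
    p <- file.path(input_dir, fname)
    if (!file.exists(p)) return(invisible())
    d <- tryCatch(read.csv(p, stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(d)) { note("error", fname, "unreadable CSV"); return(invisible()) }
    miss <- setdiff(need, names(d))
    if (length(miss))
      note("error", fname,
           paste("missing columns:", paste(miss, collapse = ", ")))
    if (!is.null(design) && "animal_id" %in% names(d) &&
        "animal_id" %in% names(design)) {
      orphan <- setdiff(unique(d$animal_id), design$animal_id)
      if (length(orphan))
        note("warning", fname,
             sprintf("animals absent from design.csv: %s",
                     paste(orphan, collapse = ", ")))
    }
    invisible()
  }
  check_table("ct.csv", c("animal_id", "group", "gene", "ct"))
  check_table("pathology.csv", c("animal_id", "group", "feature", "score"))

  mech_dir <- file.path(input_dir, "mechanics")
  if (dir.exists(mech_dir)) {
    for (fn in list.files(mech_dir, pattern = "_snapshot\\.csv$"))
      check_table(file.path("mechanics", fn),
                  c("time", "pressure", "flow", "volume"))
    for (fn in list.files(mech_dir, pattern = "_impedance\\.csv$"))
      check_table(file.path("mechanics", fn), c("freq", "re_z", "im_z"))
    for (fn in list.files(mech_dir, pattern = "_pv\\.csv$"))
      check_table(file.path("mechanics", fn),
                  c("limb", "pressure", "volume"))
  }

  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(), file = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Run the full analysis over a study bundle
#'
#' Executes morphometry (per image), mechanics fits (per animal),
#' expression normalization, and the factorial statistics over an on-disk
#' bundle (typically from [generate_cohort()], but any bundle with the
#' same layout works). Every output CSV carries the configuration hash
#' and seed in a stamped comment line; a plain-text run log records
#' per-stage counts with ISO timestamps.
#'
#' @param input_dir bundle directory.
#' @param output_dir results directory (created).
#' @param config a [study_config()].
#' @param stages which stages to run (subset of
#'   `c("morphometry", "mechanics", "expression", "stats")`; stats
#'   requires morphometry).
#' @param verbose print progress.
#' @return invisibly, a list with per-stage results and `counts`.
#' @export
run_study <- function(input_dir, output_dir,
                      config = study_config(),
                      stages = c("morphometry", "mechanics", "expression",
                                 "stats"),
                      verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log <- file(file.path(output_dir, "run.log"), "w")
  on.exit(close(log))
  log_line(log, "run_study start config_hash=%s seed=%d", hash, config$seed)

  design <- read.csv(file.path(input_dir, "design.csv"),
                     stringsAsFactors = FALSE)
  manifest_path <- file.path(input_dir, "manifest.yaml")
  ppm <- config$px_per_micron %||%
    (if (file.exists(manifest_path))
       yaml::read_yaml(manifest_path)$px_per_micron else NULL) %||% 2.764
  results <- list(config = config, config_hash = hash)
  counts <- list()
  emit <- function(df, name)
    write_stamped_csv(df, file.path(output_dir, name), hash, config$seed)

  if ("morphometry" %in% stages) {
    cfg <- mli_config(config$spacing_px, config$min_area_px, ppm,
                      config$count_direction)
    img_dir <- file.path(input_dir, "images")
    imgs <- list.files(img_dir, pattern = "\\.png$")
    rows <- lapply(imgs, function(fn) {
      aid <- sub("_img\\d+\\.png$", "", fn)
      gi <- match(aid, design$animal_id)
      if (is.na(gi))
        stop_lungmorph("lungmorph_stage_error",
                       sprintf("morphometry: image '%s' maps to no animal", fn))
      img <- tryCatch(read_calibrated_image(file.path(img_dir, fn), ppm),
                      error = function(e)
                        stop_lungmorph("lungmorph_stage_error",
                                       sprintf("morphometry: unreadable image '%s'", fn)))
      res <- mli_for_image(img, cfg)
      if (verbose && !is.null(res$failure))
        message(fn, ": ", res$failure$message)
      data.frame(image = fn, animal_id = aid, group = design$group[gi],
                 N = res$counts$N %||% NA_integer_,
                 l = res$counts$l %||% NA_integer_,
                 sum_I = res$counts$sum_I %||% NA_integer_,
                 L_M_um = res$L_M_um, stringsAsFactors = FALSE)
    })
    per_image <- do.call(rbind, rows)
    agg <- aggregate_mli(per_image)
    results$morphometry <- c(list(per_image = per_image), agg)
    counts$images_processed <- nrow(per_image)
    counts$images_failed <- sum(is.na(per_image$L_M_um))
    emit(per_image, "mli_per_image.csv")
    emit(agg$per_mouse, "mli_per_mouse.csv")
    emit(agg$per_group, "mli_per_group.csv")
    log_line(log, "morphometry: %d images processed, %d failed",
             counts$images_processed, counts$images_failed)
  }

  if ("mechanics" %in% stages) {
    mech_dir <- file.path(input_dir, "mechanics")
    fitted <- 0L; excluded <- character()
    rows <- lapply(design$animal_id, function(aid) {
      paths <- file.path(mech_dir, paste0(aid, c("_snapshot.csv",
                                                 "_impedance.csv",
                                                 "_pv.csv")))
      if (!all(file.exists(paths))) { excluded <<- c(excluded, aid); return(NULL) }
      sc <- tryCatch(fit_single_compartment(read.csv(paths[1L])),
                     lungmorph_error = function(e) NULL)
      cp <- tryCatch(fit_constant_phase(read.csv(paths[2L])),
                     lungmorph_error = function(e) NULL)
      pv <- tryCatch(pv_metrics(read.csv(paths[3L]), config$cst_pressure,
                                config$tlc_pressure),
                     lungmorph_error = function(e) NULL)
      if (is.null(sc) || is.null(cp) || is.null(pv)) {
        excluded <<- c(excluded, aid); return(NULL)
      }
      fitted <<- fitted + 1L
      gi <- match(aid, design$animal_id)
      data.frame(animal_id = aid, group = design$group[gi],
                 diet = design$diet[gi], smoke = design$smoke[gi],
                 R = sc$R, C = sc$C,
                 Rn = cp$Rn, Iaw = cp$Iaw, G = cp$G, H = cp$H,
                 alpha = cp$alpha,
                 Cst = pv$Cst, TLC = pv$TLC, Area = pv$Area,
                 stringsAsFactors = FALSE)
    })
    per_animal <- do.call(rbind, rows)
    results$mechanics <- per_animal
    counts$animals_fitted <- fitted
    counts$animals_excluded_mechanics <- length(excluded)
    if (!is.null(per_animal)) emit(per_animal, "mechanics_per_animal.csv")
    log_line(log, "mechanics: %d animals fitted, %d excluded", fitted,
             length(excluded))
  }

  if ("expression" %in% stages) {
    ct_path <- file.path(input_dir, "ct.csv")
    if (file.exists(ct_path)) {
      ct <- read.csv(ct_path, stringsAsFactors = FALSE)
      rel <- relative_expression(ct)
      ratio <- mmp9_timp1_ratio(rel)
      results$expression <- list(relative = rel, ratio = ratio)
      counts$animals_expression <- length(unique(rel$animal_id))
      emit(rel, "relative_expression.csv")
      emit(ratio$per_animal, "mmp9_timp1_per_animal.csv")
      emit(ratio$per_group, "mmp9_timp1_per_group.csv")
      log_line(log, "expression: %d animals normalized",
               counts$animals_expression)
    }
  }

  if ("stats" %in% stages) {
    endpoints <- list()
    add_endpoint <- function(name, values, animal_ids) {
      gi <- match(animal_ids, design$animal_id)
      endpoints[[name]] <<- data.frame(
        value = values, group = design$group[gi], diet = design$diet[gi],
        smoke = design$smoke[gi], stringsAsFactors = FALSE)
    }
    if (!is.null(results$morphometry))
      add_endpoint("L_M_um", results$morphometry$per_mouse$L_M_um,
                   results$morphometry$per_mouse$animal_id)
    if (!is.null(results$mechanics))
      for (v in c("R", "C", "Rn", "G", "H", "Cst", "TLC", "Area"))
        add_endpoint(v, results$mechanics[[v]],
                     results$mechanics$animal_id)
    if (!is.null(results$expression)) {
      rel <- results$expression$relative
      for (g in setdiff(unique(rel$gene), "RPL13a")) {
        d <- rel[rel$gene == g, ]
        add_endpoint(paste0("rel_", g), d$rel, d$animal_id)
      }
      ra <- results$expression$ratio$per_animal
      add_endpoint("mmp9_timp1_ratio", ra$ratio, ra$animal_id)
    }

    anova_rows <- list(); comp_rows <- list(); summ_rows <- list()
    for (nm in names(endpoints)) {
      d <- endpoints[[nm]]
      an <- tryCatch(two_way_anova(d), error = function(e) NULL)
      if (!is.null(an)) {
        an$endpoint <- nm
        anova_rows[[nm]] <- an
      }
      cmp <- tryCatch(planned_comparisons(d$value, d$group, config$pairs,
                                          config$m),
                      error = function(e) NULL)
      if (!is.null(cmp)) { cmp$endpoint <- nm; comp_rows[[nm]] <- cmp }
      gs <- group_summary(d$value, d$group)
      gs$endpoint <- nm
      summ_rows[[nm]] <- gs
    }
    stats_out <- list(anova = do.call(rbind, anova_rows),
                      comparisons = do.call(rbind, comp_rows),
                      summaries = do.call(rbind, summ_rows))

    path_path <- file.path(input_dir, "pathology.csv")
    if (file.exists(path_path)) {
      sc <- read.csv(path_path, stringsAsFactors = FALSE)
      kw <- do.call(rbind, lapply(unique(sc$feature), function(f) {
        r <- kruskal_wallis_scores(sc, f)
        data.frame(feature = f, H = r$H, df = r$df, p = r$p,
                   stringsAsFactors = FALSE)
      }))
      prev <- do.call(rbind, lapply(split(sc, sc[c("feature", "group")],
                                          drop = TRUE),
        function(d) data.frame(feature = d$feature[1L], group = d$group[1L],
                               n = nrow(d), n_present = sum(d$score > 0L),
                               prevalence = mean(d$score > 0L),
                               stringsAsFactors = FALSE)))
      rownames(prev) <- NULL
      stats_out$pathology_kw <- kw
      stats_out$pathology_prevalence <- prev
      emit(kw, "pathology_kruskal_wallis.csv")
      emit(prev, "pathology_prevalence.csv")
    }
    results$stats <- stats_out
    if (!is.null(stats_out$anova)) emit(stats_out$anova, "anova.csv")
    if (!is.null(stats_out$comparisons))
      emit(stats_out$comparisons, "planned_comparisons.csv")
    if (!is.null(stats_out$summaries))
      emit(stats_out$summaries, "group_summaries.csv")
    log_line(log, "stats: %d endpoints analyzed", length(endpoints))
    counts$endpoints_analyzed <- length(endpoints)
  }

  results$counts <- counts
  log_line(log, "run_study done")
  invisible(results)
}
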