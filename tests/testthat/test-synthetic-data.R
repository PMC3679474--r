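# Parenchyma phantoms, chord ground truth, mechanics/Ct generators, and
# the on-disk cohort bundle.

small_params <- function(...) {
  parenchyma_params(image_width = 240L, image_height = 180L,
                    target_cell_diameter = 30, ...)
}

test_that("parenchyma generation is bit-identical under a fixed seed", {
  p <- small_params(seed = 5L, macrophage_count = 2L, speckle_count = 2L)
  g1 <- generate_parenchyma_image(p)
  g2 <- generate_parenchyma_image(p)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$airspace_mask, g2$truth$airspace_mask)
  g3 <- generate_parenchyma_image(small_params(seed = 6L))
  expect_false(identical(g1$image$pixels, g3$image$pixels))
})

test_that("noiseless rendering coincides with the ground-truth mask", {
  g <- generate_parenchyma_image(small_params(seed = 3L, noise_sd = 0))
  lum <- 0.299 * g$image$pixels[, , 1] + 0.587 * g$image$pixels[, , 2] +
    0.114 * g$image$pixels[, , 3]
  expect_identical((lum > 0.9) * 1L, unname(g$truth$airspace_mask * 1L))
  expect_equal(g$truth$true_airspace_fraction,
               mean(g$truth$airspace_mask == 1L))
})

test_that("macrophage blobs lie inside airspaces and speckles on tissue", {
  pal <- parenchyma_palette()
  g <- generate_parenchyma_image(
    small_params(seed = 9L, noise_sd = 0, macrophage_count = 3L,
                 speckle_count = 3L, macrophage_diameter = 8))
  px <- g$image$pixels
  is_color <- function(col)
    px[, , 1] == col[1] & px[, , 2] == col[2] & px[, , 3] == col[3]
  mac <- is_color(pal$macrophage)
  spk <- is_color(pal$speckle)
  expect_gt(sum(mac), 0)
  expect_gt(sum(spk), 0)
  expect_true(all(g$truth$airspace_mask[mac] == 1L))
  expect_true(all(g$truth$airspace_mask[spk] == 0L))
  # each speckle is an isolated white component below the exclusion area
  comp <- oracle_filter(spk * 1L, 500)
  expect_true(all(comp == 0L))
})

test_that("oversized macrophages are rejected", {
  expect_error(
    parenchyma_params(target_cell_diameter = 20, macrophage_diameter = 25,
                      macrophage_count = 1L),
    class = "lungmorph_blob_too_large")
})

test_that("measure_true_chords matches closed forms and signals empty masks", {
  ppm <- 2.5
  band <- matrix(0L, 30, 100)
  band[6:15, ] <- 1L
  ch <- measure_true_chords(band, ppm)
  expect_equal(ch$n_chords, 10L)
  expect_equal(ch$mean_um, 100 / ppm)
  expect_error(measure_true_chords(matrix(0L, 5, 5), ppm),
               class = "lungmorph_no_chords")
})

test_that("measure_true_chords equals an independent state-machine scan", {
  set.seed(42)
  for (i in 1:20) {
    m <- random_mask(25, 40, p = runif(1, 0.2, 0.8))
    if (!any(m == 1L)) next
    lens <- oracle_chords(m)
    got <- measure_true_chords(m, 2.764)
    expect_equal(got$n_chords, length(lens))
    expect_equal(got$mean_px, mean(lens))
    expect_equal(got$mean_um, mean(lens) / 2.764)
  }
})

test_that("PV loop generator honours its closed forms", {
  lp <- generate_pv_loop(1.05, 0.95, 0.12, hysteresis_offset = 0,
                         noise_sd = 0)
  infl <- lp[lp$limb == "inflation", ]
  defl <- lp[lp$limb == "deflation", ]
  expect_equal(infl$volume[order(infl$pressure)],
               defl$volume[order(defl$pressure)])
  expect_equal(infl$volume[infl$pressure == 0], 1.05 - 0.95)
  expect_equal(pv_metrics(lp)$Area, 0, tolerance = 1e-12)
  expect_error(generate_pv_loop(1, 1.2, 0.1))   # A > B violated
  expect_error(generate_pv_loop(1.05, 0.95, 0.12,
                                pressures = c(0, 10, 5, 30)))
})

test_that("impedance generator matches the constant-phase closed form", {
  sp <- generate_impedance(0.3, 0.005, 4, 4, noise_sd = 0)
  expect_equal(attr(sp, "truth")$alpha, 0.5)
  f1 <- 7
  sp1 <- generate_impedance(0.3, 0, 4, 20, freqs = f1, noise_sd = 0)
  alpha <- (2 / pi) * atan(20 / 4)
  expect_equal(sp1$re_z, 0.3 + 4 / (2 * pi * f1)^alpha)
  expect_equal(sp1$im_z, -20 / (2 * pi * f1)^alpha)
  expect_error(generate_impedance(0.3, 0.005, 4, 20, freqs = c(0, 5)))
})

test_that("Ct generator programs exact fold-changes when noiseless", {
  gp <- default_group_params()
  for (g in names(gp)) gp[[g]]$expression[] <- 0
  des0 <- cohort_design(mice_per_group = 3L, group_params = gp)
  ct0 <- generate_ct_table(des0, ct_noise_sd = 0)
  rel0 <- relative_expression(ct0)
  base <- c(RPL13a = 18, MMP9 = 26, TIMP1 = 24, A1AT = 22)
  for (g in unique(rel0$gene)) {
    expected <- 2^(-(base[[g]] - base[["RPL13a"]]))
    expect_equal(rel0$rel[rel0$gene == g], rep(expected, 12),
                 tolerance = 1e-12)
  }
  # one group's MMP9 up by 1 log2 doubles its relative expression
  gp2 <- gp
  gp2[["VDD-CSE"]]$expression["MMP9"] <- 1
  rel1 <- relative_expression(
    generate_ct_table(cohort_design(mice_per_group = 3L, group_params = gp2),
                      ct_noise_sd = 0))
  m_vdd <- rel1$rel[rel1$gene == "MMP9" & rel1$group == "VDD-CSE"]
  m_ctl <- rel1$rel[rel1$gene == "MMP9" & rel1$group == "CD-NS"]
  expect_equal(mean(m_vdd) / mean(m_ctl), 2, tolerance = 1e-12)
})

test_that("pathology generator respects prevalence of zero and binarization", {
  des <- cohort_design(mice_per_group = 4L)
  sc <- generate_pathology_scores(des)
  expect_true(all(sc$score %in% 0:3))
  expect_identical(sc$present, as.integer(sc$score > 0L))
  # CD-CSE airway inflammation prevalence is configured at 0
  expect_true(all(sc$score[sc$group == "CD-CSE" &
                             sc$feature == "airway_inflammation"] == 0L))
})

test_that("cohort bundles are complete and byte-identical across runs", {
  ov <- list(image_width = 120L, image_height = 90L,
             target_cell_diameter = 25, macrophage_count = 1L,
             speckle_count = 1L, macrophage_diameter = 6)
  des <- cohort_design(mice_per_group = 1L, images_per_mouse = 1L,
                       master_seed = 11L, image_overrides = ov)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  suppressWarnings({
    generate_cohort(des, d1)
    generate_cohort(des, d2)
  })
  expect_length(list.files(file.path(d1, "images")), 4L)
  expect_equal(nrow(read.csv(file.path(d1, "design.csv"))), 4L)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  expect_error(generate_cohort(des, d1), "overwrite")
})
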