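# Segmentation, component filtering, line grid, intercept counting, L_M.

test_that("two-tone images segment exactly and deterministically", {
  st <- stripe_image(W = 200, H = 120, air = 40, tissue = 30)
  m1 <- segment_airspace(st$image)
  m2 <- segment_airspace(st$image)
  expect_identical(m1, st$mask)
  expect_identical(m1, m2)
})

test_that("segmentation of noisy phantoms agrees with an Otsu oracle", {
  p <- parenchyma_params(image_width = 300L, image_height = 220L,
                         target_cell_diameter = 30, noise_sd = 0.02,
                         seed = 21L)
  g <- generate_parenchyma_image(p)
  km <- segment_airspace(g$image)
  ot <- oracle_otsu_mask(g$image$pixels)
  expect_gte(mean(km == ot), 0.99)
})

test_that("single-color images are degenerate, with a mid-gray fallback", {
  white <- calibrated_image(array(0.95, c(10, 12, 3)))
  dark <- calibrated_image(array(0.2, c(10, 12, 3)))
  expect_error(segment_airspace(white),
               class = "lungmorph_degenerate_image")
  expect_true(all(segment_airspace(white, degenerate = "midgray") == 1L))
  expect_true(all(segment_airspace(dark, degenerate = "midgray") == 0L))
})

test_that("component filter applies the strict sub-500-px rule", {
  # 20 x 25 rectangle = exactly 500 px -> retained
  m <- matrix(0L, 60, 60)
  m[11:30, 11:35] <- 1L
  expect_identical(filter_small_airspaces(m, 500)[11:30, 11:35],
                   m[11:30, 11:35])
  # removing one pixel makes it 499 -> removed entirely
  m2 <- m
  m2[11, 11] <- 0L
  expect_true(all(filter_small_airspaces(m2, 500) == 0L))
  # all-tissue mask unchanged
  z <- matrix(0L, 8, 9)
  expect_true(all(filter_small_airspaces(z, 500) == 0L))
})

test_that("component filter matches a flood-fill oracle and is idempotent", {
  set.seed(7)
  for (i in 1:30) {
    m <- random_mask(25, 35, p = runif(1, 0.2, 0.7))
    f1 <- filter_small_airspaces(m, 20)
    expect_identical(strip_mask(f1), strip_mask(oracle_filter(m, 20)))
    f2 <- filter_small_airspaces(f1, 20)
    expect_identical(strip_mask(f2), strip_mask(f1))          # idempotent
    expect_lte(sum(f1), sum(m))                               # never grows
  }
})

test_that("line grid reproduces the standard-field geometry", {
  g <- build_line_grid(1200, 1600, 69)
  expect_equal(g$N, 18L)
  expect_equal(g$l, 1600L)
  expect_equal(g$total_length_px, 28800)
  expect_equal(round(g$total_length_px / 2.764), 10420)
  # 25 microns at the standard calibration is 69 px
  expect_equal(round(25 * 2.764), 69)
  expect_equal(build_line_grid(1, 500, 10)$rows, 1L)
  expect_equal(build_line_grid(50, 500, 200)$rows, 1L)  # spacing > H-1
})

test_that("transition counting is one-directional with border rule", {
  st <- stripe_image()  # 1600 x 1200, 100 air + 100 tissue
  grid <- build_line_grid(1200, 1600, 69)
  cnt <- count_transitions(st$mask, grid)
  expect_equal(cnt$sum_I, 144L)   # 8 per line x 18 lines
  expect_equal(cnt$sum_I, oracle_transitions(st$mask, grid$rows))
  both <- count_transitions(st$mask, grid, direction = "both")
  expect_equal(both$sum_I, oracle_transitions(st$mask, grid$rows, "both"))
  # all airspace: no transitions
  expect_equal(count_transitions(matrix(1L, 100, 80),
                                 build_line_grid(100, 80, 30))$sum_I, 0L)
  # single airspace column on the right border: nothing to its right
  m <- matrix(0L, 90, 70)
  m[, 70] <- 1L
  expect_equal(count_transitions(m, build_line_grid(90, 70, 20))$sum_I, 0L)
})

test_that("transition counting matches the brute-force oracle on fuzz", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_mask(30, 45, p = runif(1, 0.2, 0.8))
    grid <- build_line_grid(30, 45, sample(3:12, 1))
    for (dir in c("air_to_tissue", "both")) {
      expect_equal(count_transitions(m, grid, dir)$sum_I,
                   oracle_transitions(m, grid$rows, dir))
    }
  }
})

test_that("L_M follows the intercept formula and its limits", {
  st <- stripe_image()
  grid <- build_line_grid(1200, 1600, 69)
  cnt <- count_transitions(st$mask, grid)
  lm_um <- compute_mli(cnt, 2.764)
  expect_equal(lm_um, (18 * 1600 / 144) / 2.764)  # = 200 px in microns
  expect_equal(lm_um, 72.36, tolerance = 0.005)
  # doubling the calibration halves L_M
  expect_equal(compute_mli(cnt, 2 * 2.764), lm_um / 2)
  # theoretical ceiling: a transition at every pixel
  ceiling_cnt <- list(N = 18L, l = 1600L, sum_I = 18L * 1600L)
  expect_equal(compute_mli(ceiling_cnt, 2.764), 1 / 2.764)
  # no intercepts is a distinct failure, not 0 or Inf
  expect_error(compute_mli(list(N = 18L, l = 1600L, sum_I = 0L), 2.764),
               class = "lungmorph_no_intercepts")
})

test_that("stripe phantoms give L_M = period/calibration exactly", {
  for (spec in list(c(100, 100), c(60, 40), c(150, 50))) {
    st <- stripe_image(W = 1600, H = 300, air = spec[1], tissue = spec[2])
    res <- mli_for_image(st$image)
    expect_equal(res$L_M_um, (spec[1] + spec[2]) / 2.764, tolerance = 1e-12)
  }
})

test_that("tissue-colored intra-airspace blobs can only lower L_M", {
  base <- parenchyma_params(image_width = 480L, image_height = 360L,
                            target_cell_diameter = 40, seed = 13L,
                            noise_sd = 0.02)
  withmac <- parenchyma_params(image_width = 480L, image_height = 360L,
                               target_cell_diameter = 40, seed = 13L,
                               noise_sd = 0.02, macrophage_count = 8L)
  lm0 <- mli_for_image(generate_parenchyma_image(base)$image)$L_M_um
  lm1 <- mli_for_image(generate_parenchyma_image(withmac)$image)$L_M_um
  expect_lt(lm1, lm0)
})

test_that("measured L_M tracks the exhaustive-chord truth across sizes", {
  sizes <- c(26, 32, 40, 50, 62)
  lm <- truth <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    p <- parenchyma_params(image_width = 480L, image_height = 360L,
                           target_cell_diameter = sizes[i], noise_sd = 0,
                           seed = 100L + i)
    g <- generate_parenchyma_image(p)
    truth[i] <- g$truth$true_mean_airspace_chord
    lm[i] <- mli_for_image(g$image)$L_M_um
  }
  expect_equal(cor(lm, truth, method = "spearman"), 1)
})

test_that("aggregation averages images within mouse, then mice within group", {
  per_image <- data.frame(
    image = sprintf("i%d.png", 1:6),
    animal_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
    group = c("A", "A", "A", "A", "B", "B"),
    L_M_um = c(30, 34, 32, 32, NA, NA))
  expect_warning(agg <- aggregate_mli(per_image), "m3")
  expect_equal(agg$per_mouse$L_M_um[agg$per_mouse$animal_id == "m1"], 32)
  ga <- agg$per_group[agg$per_group$group == "A", ]
  expect_equal(ga$n, 2L)
  expect_equal(ga$mean, 32)
  expect_equal(ga$sem, 0)
})
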