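# Factorial ANOVA, planned comparisons, Kruskal-Wallis, group summaries.

make_sample <- function(means, n, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(diet = c("CD", "VDD"), smoke = c("NS", "CSE"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(diet = cells$diet[i], smoke = cells$smoke[i],
               value = means[i] + rnorm(n, 0, sd))))
}

test_that("all-equal samples yield the zero-variance convention", {
  a <- two_way_anova(make_sample(c(5, 5, 5, 5), 4))
  expect_equal(a$sum_sq, rep(0, 4))
  expect_equal(a$F[1:3], rep(0, 3))
  expect_equal(a$p[1:3], rep(1, 3))
})

test_that("balanced single-cell offsets give the closed-form partition", {
  n <- 5; delta <- 2
  d <- make_sample(c(0, 0, 0, delta), n)
  a <- two_way_anova(d)
  ss <- setNames(a$sum_sq, a$effect)
  expect_equal(unname(ss["diet:smoke"]), n * delta^2 / 4)
  expect_equal(unname(ss["diet"]), n * delta^2 / 4)
  expect_equal(unname(ss["smoke"]), n * delta^2 / 4)
  expect_equal(unname(ss["residual"]), 0)
  oracle <- oracle_anova_ss3(d)
  expect_equal(unname(ss[c("diet", "smoke", "diet:smoke")]),
               unname(oracle[c("diet", "smoke", "interaction")]),
               tolerance = 1e-9)
})

test_that("balanced partitions sum to the total sum of squares", {
  d <- make_sample(c(1, 3, 2, 5), 6, sd = 1, seed = 2)
  a <- two_way_anova(d)
  expect_equal(sum(a$sum_sq), sum((d$value - mean(d$value))^2),
               tolerance = 1e-9)
})

test_that("unbalanced designs use Type III sums of squares", {
  set.seed(14)
  d <- make_sample(c(1, 3, 2, 5), 9, sd = 1.5)
  d <- d[-c(1, 2, 11, 20, 21, 22), ]    # unbalance the cells
  a <- two_way_anova(d)
  ss <- setNames(a$sum_sq, a$effect)
  oracle <- oracle_anova_ss3(d)
  expect_equal(unname(ss[c("diet", "smoke", "diet:smoke")]),
               unname(oracle[c("diet", "smoke", "interaction")]),
               tolerance = 1e-8)
  expect_equal(unname(ss["residual"]), unname(oracle["residual"]),
               tolerance = 1e-8)
})

test_that("main-effect F matches the squared marginal t when the other
           factor contributes nothing", {
  # duplicate each diet's residual vector across the two smoke levels so
  # that the smoke and interaction sums of squares are exactly zero
  set.seed(5)
  n <- 8
  v_cd <- 1 + rnorm(n); v_vdd <- 2.5 + rnorm(n)
  d <- rbind(
    data.frame(diet = "CD", smoke = "NS", value = v_cd),
    data.frame(diet = "CD", smoke = "CSE", value = v_cd),
    data.frame(diet = "VDD", smoke = "NS", value = v_vdd),
    data.frame(diet = "VDD", smoke = "CSE", value = v_vdd))
  a <- two_way_anova(d)
  ss <- setNames(a$sum_sq, a$effect)
  expect_equal(unname(ss["smoke"]), 0, tolerance = 1e-12)
  expect_equal(unname(ss["diet:smoke"]), 0, tolerance = 1e-12)
  tt <- t.test(value ~ diet, data = d, var.equal = TRUE)
  f_diet <- a$F[a$effect == "diet"]
  N <- nrow(d)
  # identical SS, residual df N-4 (two-way) vs N-2 (marginal t)
  expect_equal(unname(f_diet),
               unname(tt$statistic)^2 * (N - 4) / (N - 2),
               tolerance = 1e-9)
})

test_that("empty or underfilled cells are rejected by name", {
  d <- make_sample(c(1, 2, 3, 4), 3)
  d2 <- d[!(d$diet == "VDD" & d$smoke == "CSE"), ]
  err <- tryCatch(two_way_anova(d2), error = function(e) e)
  expect_s3_class(err, "lungmorph_empty_cell")
  expect_match(conditionMessage(err), "VDD")
  d3 <- rbind(d2, data.frame(diet = "VDD", smoke = "CSE", value = 1))
  expect_error(two_way_anova(d3), ">= 2")
})

test_that("Bonferroni adjustment is m*p capped at one", {
  set.seed(6)
  v <- c(rnorm(6, 0), rnorm(6, 4), rnorm(6, 0.1))
  g <- rep(c("A", "B", "C"), each = 6)
  pairs <- list(c("B", "A"), c("C", "A"), c("B", "C"))
  pc <- planned_comparisons(v, g, pairs)
  expect_equal(pc$p_bonferroni, pmin(1, 3 * pc$p_raw))
  expect_true(all(pc$p_bonferroni <= 1))
  expect_true(all(pc$p_bonferroni >= pc$p_raw))
  # identical groups: raw p of 1 stays capped at 1
  v2 <- rep(c(1, 2, 3), 2)
  pc2 <- planned_comparisons(c(v2, v2), rep(c("A", "B"), each = 6),
                             list(c("A", "B")), m = 5)
  expect_equal(pc2$p_raw, 1, tolerance = 1e-9)
  expect_equal(pc2$p_bonferroni, 1)
  expect_error(planned_comparisons(c(1, 1, 2), c("A", "A", "B"),
                                   list(c("A", "B"))), "fewer than 2")
})

test_that("planned-comparison power matches the analytic Welch power", {
  n <- 11
  analytic <- stats::power.t.test(n = n, delta = 1, sd = 1,
                                  sig.level = 0.05)$power
  set.seed(10)
  hits <- replicate(2000, {
    v <- c(rnorm(n, 0), rnorm(n, 1))
    g <- rep(c("A", "B"), each = n)
    planned_comparisons(v, g, list(c("B", "A")), m = 1)$p_bonferroni < 0.05
  })
  expect_lt(abs(mean(hits) - analytic), 0.035)
})

test_that("Kruskal-Wallis on binarized scores matches the rank oracle", {
  sc <- data.frame(group = rep(c("A", "B"), each = 3), feature = "f",
                   score = c(0, 0, 0, 2, 1, 3))
  r <- kruskal_wallis_scores(sc, "f")
  expect_equal(r$H, oracle_kw(c(0, 0, 0, 1, 1, 1), sc$group))
  expect_equal(r$p, 1 - pchisq(r$H, 1))
  # all-identical convention
  z <- data.frame(group = rep(c("A", "B"), each = 3), feature = "f",
                  score = 0L)
  rz <- kruskal_wallis_scores(z, "f")
  expect_equal(rz$H, 0)
  expect_equal(rz$p, 1)
})

test_that("Kruskal-Wallis equals the oracle on fuzzed binary tables", {
  set.seed(12)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    ns <- sample(3:8, k, replace = TRUE)
    sc <- data.frame(group = rep(LETTERS[1:k], ns), feature = "f",
                     score = rbinom(sum(ns), 1L, runif(1, 0.2, 0.8)) *
                       sample(1:3, sum(ns), TRUE))
    r <- kruskal_wallis_scores(sc, "f")
    v <- as.integer(sc$score > 0)
    if (length(unique(v)) == 1L) {
      expect_equal(r$H, 0)
    } else {
      expect_equal(r$H, oracle_kw(v, sc$group), tolerance = 1e-12)
      expect_equal(r$p, 1 - pchisq(r$H, k - 1), tolerance = 1e-12)
    }
  }
})

test_that("group summaries report SEM with the n-1 denominator", {
  gs <- group_summary(c(1, 2, 3), rep("A", 3))
  expect_equal(gs$mean, 2)
  expect_equal(gs$sem, 1 / sqrt(3))
  gs2 <- group_summary(c(4, 4, 4, 7), c("A", "A", "A", "B"))
  expect_equal(gs2$sem[gs2$group == "A"], 0)
  expect_true(is.na(gs2$sem[gs2$group == "B"]))
  expect_false(gs2$sem_defined[gs2$group == "B"])
  set.seed(20)
  for (i in 1:10) {
    v <- rnorm(sample(2:9, 1))
    gs3 <- group_summary(v, rep("G", length(v)))
    expect_equal(gs3$mean, mean(v))
    expect_equal(gs3$sem, sd(v) / sqrt(length(v)))
  }
})
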