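# Inferential layer: 2x2 between-subjects ANOVA with Bonferroni-adjusted
# planned comparisons, Kruskal-Wallis on binarized pathology scores, and
# mean +/- SEM summaries.

#' Two-way between-subjects ANOVA
#'
#' Diet x smoke factorial ANOVA on per-animal values. Balanced data
#' follow the textbook orthogonal partition (SS_total = SS_diet +
#' SS_smoke + SS_interaction + SS_error); unbalanced data use Type III
#' sums of squares with sum-to-zero contrasts, which coincides with the
#' textbook partition when balanced. The degenerate all-values-equal case
#' is reported by convention as SS = 0, F = 0, p = 1 for every effect.
#'
#' @param sample data.frame with columns `value`, `diet`, `smoke`
#'   (two levels each, >= 2 observations per cell).
#' @return data.frame with one row per effect (`diet`, `smoke`,
#'   `diet:smoke`, `residual`) and columns `sum_sq`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(sample) {
  stopifnot(all(c("value", "diet", "smoke") %in% names(sample)))
  sample$diet <- factor(sample$diet)
  sample$smoke <- factor(sample$smoke)
  if (nlevels(sample$diet) != 2L || nlevels(sample$smoke) != 2L)
    stop("each factor must have exactly two levels")
  counts <- table(sample$diet, sample$smoke)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    stop_lungmorph("lungmorph_empty_cell",
                   sprintf("empty design cell: diet=%s, smoke=%s",
                           levels(sample$diet)[empty[1L]],
                           levels(sample$smoke)[empty[2L]]))
  }
  if (any(counts < 2L))
    stop("need >= 2 observations per cell")

  effects <- c("diet", "smoke", "diet:smoke")
  if (var(sample$value) == 0) {
    return(data.frame(
      effect = c(effects, "residual"),
      sum_sq = 0, df = c(1L, 1L, 1L, nrow(sample) - 4L),
      F = c(0, 0, 0, NA), p = c(1, 1, 1, NA)))
  }

  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op), add = TRUE)
  fit <- lm(value ~ diet * smoke, data = sample)
  rss_full <- sum(resid(fit)^2)
  ss_total <- sum((sample$value - mean(sample$value))^2)
  if (rss_full <= 1e-12 * ss_total) {
    # an exactly saturated fit: car::Anova refuses a zero residual, so the
    # Type III partition is taken from the model matrix directly, with the
    # convention F = Inf, p = 0 for non-zero effects
    X <- stats::model.matrix(~ diet * smoke, data = sample)
    rss_wo <- function(col)
      sum(lm.fit(X[, -col, drop = FALSE], sample$value)$residuals^2)
    ss <- c(rss_wo(2L), rss_wo(3L), rss_wo(4L)) - rss_full
    nz <- ss > 1e-12 * ss_total
    return(data.frame(
      effect = c(effects, "residual"),
      sum_sq = c(ss, rss_full),
      df = c(1L, 1L, 1L, nrow(sample) - 4L),
      F = c(ifelse(nz, Inf, 0), NA),
      p = c(ifelse(nz, 0, 1), NA)))
  }
  a3 <- car::Anova(fit, type = 3)
  pick <- function(nm) a3[rownames(a3) == nm, , drop = FALSE]
  rows <- lapply(c("diet", "smoke", "diet:smoke", "Residuals"), pick)
  out <- data.frame(
    effect = c(effects, "residual"),
    sum_sq = vapply(rows, function(r) r[["Sum Sq"]], numeric(1L)),
    df = vapply(rows, function(r) r[["Df"]], numeric(1L)),
    F = c(vapply(rows[1:3], function(r) r[["F value"]], numeric(1L)), NA),
    p = c(vapply(rows[1:3], function(r) r[["Pr(>F)"]], numeric(1L)), NA))
  out
}

#' Default planned comparison set
#'
#' Each treated group against the control group, plus the combined-insult
#' group against each single-insult group — the contrasts a 2x2
#' diet-by-smoke emphysema study reports.
#'
#' @param control control group label.
#' @export
default_comparison_pairs <- function(control = "CD-NS") {
  list(c("CD-CSE", control),
       c("VDD-NS", control),
       c("VDD-CSE", control),
       c("VDD-CSE", "CD-CSE"),
       c("VDD-CSE", "VDD-NS"))
}

#' Pre-planned pairwise comparisons with Bonferroni adjustment
#'
#' Two-sample Welch t test for each named pair of groups; adjusted
#' p = min(1, m * p_raw) with family size `m` (default: the number of
#' pairs).
#'
#' @param values numeric vector of per-animal values.
#' @param groups group label per value.
#' @param pairs list of length-2 character vectors; see
#'   [default_comparison_pairs()].
#' @param m Bonferroni family size.
#' @return data.frame with columns `group1`, `group2`, `estimate`
#'   (mean1 - mean2), `t`, `df`, `p_raw`, `p_bonferroni`.
#' @export
planned_comparisons <- function(values, groups,
                                pairs = default_comparison_pairs(),
                                m = length(pairs)) {
  stopifnot(length(values) == length(groups), m >= 1)
  rows <- lapply(pairs, function(pr) {
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    if (length(x) < 2L || length(y) < 2L)
      stop(sprintf("group '%s' or '%s' has fewer than 2 animals",
                   pr[1L], pr[2L]))
    tt <- t.test(x, y, var.equal = FALSE)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               estimate = mean(x) - mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, m * tt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis test on pathology scores
#'
#' Compares one pathology feature across groups with the Kruskal-Wallis
#' rank test (standard tie correction; binary presence/absence data are
#' maximally tied). By default the four-tier scores are binarized to
#' presence (score > 0) before testing, matching the conversion a
#' sparse-score study applies; `use = "score"` tests the raw 0-3 scale.
#' The all-values-identical case is reported by convention as H = 0,
#' p = 1.
#'
#' @param scores data.frame with columns `group`, `feature`, `score`
#'   (integer 0-3).
#' @param feature which feature to test.
#' @param use `"presence"` (default) or `"score"`.
#' @return list with `H`, `df`, `p`, `feature`, `use`.
#' @export
kruskal_wallis_scores <- function(scores, feature,
                                  use = c("presence", "score")) {
  use <- match.arg(use)
  stopifnot(all(c("group", "feature", "score") %in% names(scores)))
  d <- scores[scores$feature == feature, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no rows for feature '%s'", feature))
  if (!all(d$score %in% 0:3)) stop("scores must lie in 0..3")
  g <- factor(d$group)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  v <- if (use == "presence") as.integer(d$score > 0L) else d$score
  if (length(unique(v)) == 1L)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1, feature = feature,
                use = use))
  kt <- kruskal.test(v, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
       feature = feature, use = use)
}

#' Group mean, SEM and n
#'
#' SEM is the sample standard deviation (n-1 denominator) over sqrt(n).
#' Groups of one animal have an undefined SEM, reported as NA and flagged,
#' never as 0.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return data.frame with columns `group`, `n`, `mean`, `sem`,
#'   `sem_defined`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) >= 1L)
  if (anyNA(values)) stop("values must not contain NA")
  out <- do.call(rbind, lapply(split(values, groups), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
               sem_defined = length(v) > 1L)
  }))
  out <- cbind(group = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
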