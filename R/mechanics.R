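# Fitters for the three ventilator-derived mechanics readouts.

#' Fit the single-compartment equation of motion
#'
#' Ordinary least squares of \eqn{P(t) = R\,\dot V(t) + V(t)/C + P_0} over
#' all samples of a fixed-frequency oscillation record; the closed-form
#' linear solve a single-compartment ("Snapshot") perturbation feeds.
#'
#' @param rec data.frame with columns `time`, `pressure`, `flow`, `volume`
#'   (equal lengths >= 3, time strictly increasing).
#' @return list with `R` (cmH2O.s/mL), `C` (mL/cmH2O), `P0` (cmH2O), `rss`.
#' @export
fit_single_compartment <- function(rec) {
  need <- c("time", "pressure", "flow", "volume")
  stopifnot(all(need %in% names(rec)))
  if (nrow(rec) < 3L) stop("need at least 3 samples")
  if (is.unsorted(rec$time, strictly = TRUE))
    stop("`time` must be strictly increasing")
  X <- cbind(1, rec$flow, rec$volume)
  if (qr(X)$rank < 3L)
    stop_lungmorph("lungmorph_singular_fit",
                   "rank-deficient design: R and C are not jointly identifiable")
  fit <- lm.fit(X, rec$pressure)
  b <- fit$coefficients
  if (!is.finite(b[3L]) || b[3L] == 0)
    stop_lungmorph("lungmorph_singular_fit", "elastance term vanished; C undefined")
  list(R = unname(b[2L]), C = unname(1 / b[3L]), P0 = unname(b[1L]),
       rss = sum(fit$residuals^2))
}

#' Fit the constant-phase impedance model
#'
#' Minimizes \eqn{\sum_f |Z(f) - [R_n + j 2\pi f I_{aw} +
#' (G - jH)/(2\pi f)^\alpha]|^2} with \eqn{\alpha} tied to
#' \eqn{(2/\pi)\mathrm{atan}(H/G)}, by bounded Levenberg-Marquardt least
#' squares on the stacked real/imaginary residuals. Three fixed starting
#' points are tried and the lowest-residual solution returned, so the fit
#' is deterministic given the data; negative-parameter solutions are
#' excluded by the lower bounds.
#'
#' @param spec data.frame with columns `freq`, `re_z`, `im_z` (>= 4
#'   frequencies, all > 0, strictly increasing).
#' @return list with `Rn`, `Iaw`, `G`, `H`, `alpha`, `rss`, `converged`,
#'   and `start_rss` (residual at each multistart point).
#' @export
fit_constant_phase <- function(spec) {
  stopifnot(all(c("freq", "re_z", "im_z") %in% names(spec)))
  f <- spec$freq
  if (length(f) < 4L) stop("need >= 4 frequencies for 4 free parameters")
  if (any(f <= 0)) stop("frequencies must be > 0")
  if (is.unsorted(f, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  w <- 2 * pi * f
  z_re <- spec$re_z; z_im <- spec$im_z
  resid_fn <- function(p) {
    alpha <- (2 / pi) * atan(p[4L] / p[3L])
    wa <- w^alpha
    c(z_re - (p[1L] + p[3L] / wa),
      z_im - (w * p[2L] - p[4L] / wa))
  }
  starts <- list(c(0.2, 0.001, 1, 5),
                 c(0.5, 0.010, 5, 25),
                 c(1.0, 0.005, 10, 50))
  lower <- c(0, 0, 1e-8, 1e-8)
  best <- NULL
  start_rss <- vapply(starts, function(s) sum(resid_fn(s)^2), numeric(1L))
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop_lungmorph("lungmorph_fit_failed",
                   "constant-phase fit failed from every starting point")
  p <- best$fit$par
  list(Rn = p[1L], Iaw = p[2L], G = p[3L], H = p[4L],
       alpha = (2 / pi) * atan(p[4L] / p[3L]),
       rss = best$rss,
       converged = best$fit$info %in% 1:4,
       start_rss = start_rss)
}

#' Pressure-volume loop metrics
#'
#' Fits the Salazar-Knowles relation \eqn{V = A - B e^{-KP}} to the
#' deflation limb by nonlinear least squares, then reports static
#' compliance \eqn{C_{st} = BK e^{-K P^*}} at `cst_pressure`, total lung
#' capacity as the fitted volume at `tlc_pressure`, and hysteresis as the
#' absolute shoelace area of the closed loop polygon. When the exponential
#' fit fails or degenerates (K near 0, i.e. an essentially linear limb), a
#' linear fallback `V = c P + b` is used: Cst = c, TLC from the line.
#'
#' @param loop a [generate_pv_loop()]-shaped data.frame (`limb`,
#'   `pressure`, `volume`) with >= 4 deflation points.
#' @param cst_pressure pressure (cmH2O) at which Cst is evaluated
#'   (default 5).
#' @param tlc_pressure maximal inflation pressure defining TLC
#'   (default 30).
#' @return list with `Cst` (mL/cmH2O), `TLC` (mL), `Area` (mL.cmH2O),
#'   `A`, `B`, `K` (NA under the linear fallback), `model`
#'   ("salazar-knowles" or "linear"), `rss`.
#' @export
pv_metrics <- function(loop, cst_pressure = 5, tlc_pressure = 30) {
  stopifnot(all(c("limb", "pressure", "volume") %in% names(loop)))
  defl <- loop[loop$limb == "deflation", , drop = FALSE]
  infl <- loop[loop$limb == "inflation", , drop = FALSE]
  if (nrow(defl) < 4L)
    stop_lungmorph("lungmorph_fit_failed",
                   "fewer than 4 deflation points; PV fit undefined")
  o <- order(defl$pressure)
  P <- defl$pressure[o]; V <- defl$volume[o]

  sk <- tryCatch({
    fit <- minpack.lm::nlsLM(
      V ~ A - B * exp(-K * P),
      start = list(A = max(V), B = max(max(V) - min(V), 1e-3), K = 0.1),
      lower = c(A = 0, B = 1e-9, K = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    cf <- coef(fit)
    list(cf = cf, rss = sum(resid(fit)^2))
  }, error = function(e) NULL)

  # a linear limb is the K -> 0 limit of the exponential; prefer the
  # linear model whenever it fits at least as well (ties included)
  lin <- lm(V ~ P)
  lin_rss <- sum(resid(lin)^2)
  if (!is.null(sk) && sk$rss < lin_rss && sk$cf[["K"]] >= 1e-6) {
    A <- sk$cf[["A"]]; B <- sk$cf[["B"]]; K <- sk$cf[["K"]]
    Cst <- B * K * exp(-K * cst_pressure)
    TLC <- A - B * exp(-K * tlc_pressure)
    model <- "salazar-knowles"; rss <- sk$rss
  } else {
    Cst <- unname(coef(lin)[2L])
    TLC <- unname(predict(lin, data.frame(P = tlc_pressure)))
    A <- NA_real_; B <- NA_real_; K <- NA_real_
    model <- "linear"; rss <- lin_rss
  }

  # closed polygon: inflation by ascending P, deflation by descending P
  oi <- order(infl$pressure)
  xs <- c(infl$pressure[oi], rev(P))
  ys <- c(infl$volume[oi], rev(V))
  n <- length(xs)
  if (n >= 3L) {
    j <- c(2:n, 1L)
    Area <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
  } else Area <- 0
  list(Cst = Cst, TLC = TLC, Area = Area, A = A, B = B, K = K,
       model = model, rss = rss)
}
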