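# Synthetic forced-oscillation and pressure-volume records with known truth.

#' Generate a pressure-volume loop from the Salazar-Knowles relation
#'
#' Deflation limb \eqn{V(P) = A - B e^{-KP}}; the inflation limb sits
#' `hysteresis_offset` below it, scaled by a sine shape factor that
#' vanishes at both pressure endpoints so the loop closes. Gaussian noise
#' is added to the volumes of each limb independently.
#'
#' @param A,B,K Salazar-Knowles parameters: `A` (mL) asymptotic volume,
#'   `B` (mL) recruitable volume, `K` (1/cmH2O) curvature. Requires
#'   `A > B > 0`, `K > 0`.
#' @param pressures ascending pressure grid in cmH2O (default 0-30).
#' @param hysteresis_offset peak inflation-deflation volume separation (mL).
#' @param noise_sd volume noise sd (mL).
#' @param seed RNG seed.
#' @return data.frame of class `pv_loop` with columns `limb`
#'   (inflation/deflation), `pressure`, `volume`; generator truth in
#'   `attr(, "truth")`.
#' @export
generate_pv_loop <- function(A, B, K, pressures = seq(0, 30, by = 1),
                             hysteresis_offset = 0.05, noise_sd = 0,
                             seed = 1L) {
  if (!(A > B && B > 0 && K > 0))
    stop("require A > B > 0 and K > 0")
  if (is.unsorted(pressures, strictly = TRUE))
    stop("`pressures` must be strictly increasing")
  withr::with_seed(seed, {
    defl <- A - B * exp(-K * pressures)
    rng <- range(pressures)
    shape <- if (diff(rng) > 0)
      sin(pi * (pressures - rng[1L]) / diff(rng)) else rep(0, length(pressures))
    infl <- defl - hysteresis_offset * shape
    if (noise_sd > 0) {
      infl <- infl + rnorm(length(infl), 0, noise_sd)
      defl <- defl + rnorm(length(defl), 0, noise_sd)
    }
    loop <- rbind(
      data.frame(limb = "inflation", pressure = pressures, volume = infl),
      data.frame(limb = "deflation", pressure = rev(pressures),
                 volume = rev(defl))
    )
    attr(loop, "truth") <- list(A = A, B = B, K = K,
                                hysteresis_offset = hysteresis_offset,
                                noise_sd = noise_sd, seed = seed)
    class(loop) <- c("pv_loop", "data.frame")
    loop
  })
}

#' Generate a constant-phase input impedance spectrum
#'
#' \eqn{Z(f) = R_n + j\,2\pi f\,I_{aw} + (G - jH)/(2\pi f)^\alpha} with
#' \eqn{\alpha = (2/\pi)\,\mathrm{atan}(H/G)}. Independent Gaussian noise
#' is added to the real and imaginary parts at each frequency.
#'
#' @param Rn Newtonian (airway) resistance, cmH2O.s/mL.
#' @param Iaw airway inertance, cmH2O.s^2/mL.
#' @param G tissue damping, cmH2O/mL (> 0).
#' @param H tissue elastance, cmH2O/mL (> 0).
#' @param freqs oscillation frequencies in Hz, all > 0 (default: the
#'   1-20.5 Hz multi-frequency ladder of a small-animal ventilator prime).
#' @param noise_sd per-component noise sd (cmH2O.s/mL).
#' @param seed RNG seed.
#' @return data.frame of class `impedance_spectrum` with columns `freq`,
#'   `re_z`, `im_z`; truth (including alpha) in `attr(, "truth")`.
#' @export
generate_impedance <- function(Rn, Iaw, G, H,
                               freqs = c(1, 1.5, 2.5, 3.5, 5.5, 7.5, 9.5,
                                         11.5, 13.5, 15.5, 17.5, 19.5),
                               noise_sd = 0, seed = 1L) {
  if (any(freqs <= 0)) stop("frequencies must be > 0")
  if (!(G > 0 && H > 0)) stop("require G > 0 and H > 0")
  withr::with_seed(seed, {
    w <- 2 * pi * freqs
    alpha <- (2 / pi) * atan(H / G)
    z <- Rn + 1i * w * Iaw + (G - 1i * H) / w^alpha
    re <- Re(z); im <- Im(z)
    if (noise_sd > 0) {
      re <- re + rnorm(length(z), 0, noise_sd)
      im <- im + rnorm(length(z), 0, noise_sd)
    }
    spec <- data.frame(freq = freqs, re_z = re, im_z = im)
    attr(spec, "truth") <- list(Rn = Rn, Iaw = Iaw, G = G, H = H,
                                alpha = alpha, noise_sd = noise_sd,
                                seed = seed)
    class(spec) <- c("impedance_spectrum", "data.frame")
    spec
  })
}

#' Generate a single-frequency oscillation record
#'
#' Emulates a fixed-frequency (default 2.5 Hz) volume oscillation at the
#' trachea against a PEEP offset: sinusoidal flow, integrated volume, and
#' pressure from the single-compartment equation of motion
#' \eqn{P = R\dot V + V/C + P_0} plus Gaussian noise.
#'
#' @param R resistance, cmH2O.s/mL.
#' @param C compliance, mL/cmH2O (> 0).
#' @param P0 pressure offset (PEEP), cmH2O; default 3.
#' @param freq oscillation frequency in Hz.
#' @param amplitude volume oscillation amplitude, mL.
#' @param duration record length in s.
#' @param sample_rate samples per second.
#' @param noise_sd pressure noise sd, cmH2O.
#' @param seed RNG seed.
#' @return data.frame of class `perturbation_record` with columns `time`,
#'   `pressure`, `flow`, `volume`; truth in `attr(, "truth")`.
#' @export
generate_snapshot_record <- function(R, C, P0 = 3, freq = 2.5,
                                     amplitude = 0.2, duration = 1.2,
                                     sample_rate = 256, noise_sd = 0,
                                     seed = 1L) {
  if (C <= 0) stop("C must be > 0")
  withr::with_seed(seed, {
    t <- seq(0, duration, by = 1 / sample_rate)
    w <- 2 * pi * freq
    volume <- amplitude * sin(w * t)
    flow <- amplitude * w * cos(w * t)
    pressure <- R * flow + volume / C + P0
    if (noise_sd > 0) pressure <- pressure + rnorm(length(t), 0, noise_sd)
    rec <- data.frame(time = t, pressure = pressure, flow = flow,
                      volume = volume)
    attr(rec, "truth") <- list(R = R, C = C, P0 = P0, freq = freq,
                               noise_sd = noise_sd, seed = seed)
    class(rec) <- c("perturbation_record", "data.frame")
    rec
  })
}
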