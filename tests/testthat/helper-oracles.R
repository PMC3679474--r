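# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# explicit double-loop transition count along given rows
oracle_transitions <- function(mask, rows, direction = "air_to_tissue") {
  n <- 0L
  W <- ncol(mask)
  for (y in rows) {
    for (x in seq_len(W - 1L)) {
      if (mask[y, x] == 1L && mask[y, x + 1L] == 0L) n <- n + 1L
      if (direction == "both" && mask[y, x] == 0L && mask[y, x + 1L] == 1L)
        n <- n + 1L
    }
  }
  n
}

# queue flood-fill area filter, 8-connectivity
oracle_filter <- function(mask, min_area) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  out <- mask
  for (y0 in seq_len(H)) for (x0 in seq_len(W)) {
    if (mask[y0, x0] != 1L || seen[y0, x0]) next
    comp <- matrix(c(y0, x0), ncol = 2)
    seen[y0, x0] <- TRUE
    q <- list(c(y0, x0))
    while (length(q)) {
      p <- q[[1L]]; q <- q[-1L]
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        y <- p[1L] + dy; x <- p[2L] + dx
        if (y < 1 || y > H || x < 1 || x > W) next
        if (mask[y, x] == 1L && !seen[y, x]) {
          seen[y, x] <- TRUE
          comp <- rbind(comp, c(y, x))
          q[[length(q) + 1L]] <- c(y, x)
        }
      }
    }
    if (nrow(comp) < min_area) out[comp] <- 0L
  }
  out
}

# per-row chord scan with explicit state machine (no rle)
oracle_chords <- function(mask) {
  lens <- integer(0)
  for (y in seq_len(nrow(mask))) {
    run <- 0L
    for (x in seq_len(ncol(mask))) {
      if (mask[y, x] == 1L) run <- run + 1L
      else if (run > 0L) { lens <- c(lens, run); run <- 0L }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  lens
}

# Otsu threshold on Rec.601 luminance, 256-bin histogram
oracle_otsu_mask <- function(pixels) {
  lum <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  h <- tabulate(pmin(256L, floor(lum * 256) + 1L), 256L)
  p <- h / sum(h)
  best_t <- 0; best_var <- -1
  cum <- cumsum(p); mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  for (k in 1:255) {
    w0 <- cum[k]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    v <- (mu_t * w0 - mu[k])^2 / (w0 * w1)
    if (v > best_var) { best_var <- v; best_t <- k / 256 }
  }
  (lum > best_t) * 1L
}

# Kruskal-Wallis H with tie correction from the rank-sum definition
oracle_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gs <- split(r, groups)
  H <- 12 / (N * (N + 1)) * sum(vapply(gs, function(ri)
    length(ri) * (mean(ri) - (N + 1) / 2)^2, numeric(1)))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

# Type III sums of squares by explicit full-vs-reduced regression with
# sum-to-zero coding
oracle_anova_ss3 <- function(df) {
  d <- ifelse(df$diet == sort(unique(df$diet))[1L], 1, -1)
  s <- ifelse(df$smoke == sort(unique(df$smoke))[1L], 1, -1)
  X <- cbind(1, d, s, d * s)
  rss <- function(cols) {
    Xc <- X[, cols, drop = FALSE]
    sum(lm.fit(Xc, df$value)$residuals^2)
  }
  full <- rss(1:4)
  c(diet = rss(c(1, 3, 4)) - full,
    smoke = rss(c(1, 2, 4)) - full,
    interaction = rss(1:3) - full,
    residual = full)
}

# two-tone stripe image: vertical stripes, airspace first
stripe_image <- function(W = 1600, H = 1200, air = 100, tissue = 100,
                         px_per_micron = 2.764) {
  period <- air + tissue
  in_air <- ((seq_len(W) - 1L) %% period) < air
  mask <- matrix(rep(as.integer(in_air), each = H), H, W)
  px <- array(0, c(H, W, 3))
  pal_air <- c(1, 1, 1); pal_tis <- c(0.91, 0.62, 0.73)
  for (ch in 1:3) px[, , ch] <- ifelse(mask == 1L, pal_air[ch], pal_tis[ch])
  list(image = calibrated_image(px, px_per_micron), mask = mask)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# drop attributes (e.g. min_area_applied) for exact matrix comparison
strip_mask <- function(m) matrix(as.integer(m), nrow(m))
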