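# Internal helpers shared across modules.

# Classed error so callers can distinguish degenerate-data signals from
# programming errors. `class` is appended to "lungmorph_error".
stop_lungmorph <- function(class, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "lungmorph_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

# Rec. 601 luma weights; the scalar-intensity fallback used wherever a
# single-channel view of an RGB raster is needed.
LUMA <- c(0.299, 0.587, 0.114)

luminance <- function(pixels) {
  if (length(dim(pixels)) == 3L) {
    pixels[, , 1L] * LUMA[1L] + pixels[, , 2L] * LUMA[2L] + pixels[, , 3L] * LUMA[3L]
  } else {
    pixels
  }
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Counter scheme deriving one RNG stream per (animal, substream) pair from a
# master seed; keeps results independent of cohort iteration order and the
# derived seed inside 32-bit integer range.
derive_seed <- function(master_seed, animal_index, substream = 0L) {
  as.integer((as.numeric(master_seed) + 7919 * animal_index +
                104729 * substream) %% 2147483647)
}

is_binary_mask <- function(mask) {
  is.matrix(mask) && (is.numeric(mask) || is.logical(mask)) &&
    all(mask %in% c(0L, 1L))
}

as_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  storage.mode(mask) <- "integer"
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a
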