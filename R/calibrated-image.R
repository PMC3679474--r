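#' Calibrated RGB image
#'
#' Couples an RGB pixel raster with its spatial calibration. All
#' morphometry in the package runs on this container; the calibration the
#' study design implies is 2.764 px/micron at 400x total magnification.
#'
#' @param pixels numeric array `H x W x 3`, intensities in `[0, 1]`.
#' @param px_per_micron pixels per micron (> 0).
#' @return an object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, px_per_micron = 2.764) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (!is.numeric(px_per_micron) || length(px_per_micron) != 1L ||
      px_per_micron <= 0)
    stop("`px_per_micron` must be a single positive number")
  if (any(dim(pixels)[1:2] < 1L)) stop("image dimensions must be >= 1")
  structure(list(pixels = pixels, px_per_micron = px_per_micron),
            class = "calibrated_image")
}

#' Read a PNG image with a pixel calibration
#'
#' Grayscale input is replicated to three channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to a PNG file.
#' @param px_per_micron pixels per micron for this magnification.
#' @return a [calibrated_image()].
#' @export
read_calibrated_image <- function(path, px_per_micron = 2.764) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (dim(px)[3L] == 4L) {
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3L] == 2L) {       # gray + alpha
    px <- array(rep(px[, , 1L], 3L), dim = c(dim(px)[1:2], 3L))
  }
  calibrated_image(px, px_per_micron)
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.3f px/um (%.1f x %.1f um)\n",
              d[2L], d[1L], x$px_per_micron,
              d[2L] / x$px_per_micron, d[1L] / x$px_per_micron))
  invisible(x)
}
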