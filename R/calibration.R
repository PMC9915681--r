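#' Camera pixel calibration
#'
#' The single piece of imaging metadata the pipeline needs: the physical size
#' of one camera pixel. Every size-dependent operation (structuring elements,
#' minimum peak separation, crop margins, probe windows) is specified in
#' micrometres and converted to pixels through this calibration, which is what
#' lets the same pipeline run on images from different microscopes.
#'
#' @param pixel_size Physical length of one pixel, in micrometres per pixel.
#'   Must be a single finite value > 0.
#' @param magnification_note Optional free-text provenance (objective, camera).
#' @return An object of class `"pixel_calibration"`.
#' @examples
#' cal <- pixel_calibration(0.325, "40x Keyence BZ-X710")
#' to_pixels(1.5, cal)
#' @export
pixel_calibration <- function(pixel_size, magnification_note = NULL) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a single finite value > 0 (um/pixel)")
  }
  structure(
    list(pixel_size = as.numeric(pixel_size),
         magnification_note = magnification_note),
    class = "pixel_calibration"
  )
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("Pixel calibration: %g um/pixel", x$pixel_size))
  if (!is.null(x$magnification_note)) cat(" (", x$magnification_note, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Convert a physical length to a pixel count
#'
#' Half-up rounding of `length_um / pixel_size`, floored at 1 pixel for any
#' strictly positive length so that structuring elements never degenerate at
#' coarse pixel sizes. A zero length maps to zero pixels.
#'
#' @param length_um Physical length(s) in micrometres, each >= 0.
#' @param calibration A [pixel_calibration()].
#' @return Integer vector of pixel counts.
#' @export
to_pixels <- function(length_um, calibration) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  if (!is.numeric(length_um) || any(!is.finite(length_um)) || any(length_um < 0)) {
    stop("length_um must be finite and >= 0")
  }
  px <- as.integer(round(length_um / calibration$pixel_size))
  px[length_um > 0 & px < 1L] <- 1L
  px
}

# odd pixel count >= 1 for symmetric structuring elements
to_pixels_odd <- function(length_um, calibration) {
  px <- to_pixels(length_um, calibration)
  px + (px %% 2L == 0L)
}
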