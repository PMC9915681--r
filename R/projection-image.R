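#' Calibrated 2-D projection image
#'
#' The pipeline's universal carrier: a 2-D non-negative intensity field
#' (rows x cols, row 1 at the image top) together with its pixel calibration
#' and bit depth. Intensities are kept in raw camera units; nothing rescales
#' them on load.
#'
#' @param intensities Numeric matrix of raw intensities (rows x cols).
#' @param calibration A [pixel_calibration()].
#' @param bit_depth 8 or 16. If `NULL`, inferred from the intensity range.
#' @param source_path Optional provenance string.
#' @return An object of class `"projection_image"`.
#' @export
projection_image <- function(intensities, calibration, bit_depth = NULL,
                             source_path = NA_character_) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  stopifnot(inherits(calibration, "pixel_calibration"))
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (is.null(bit_depth)) bit_depth <- if (max(intensities) > 255) 16L else 8L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (max(intensities) > 2^bit_depth - 1) {
    stop("intensities exceed the stated bit depth")
  }
  structure(
    list(intensities = intensities, calibration = calibration,
         bit_depth = bit_depth, source_path = source_path),
    class = "projection_image"
  )
}

#' @export
print.projection_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "Projection image: %d x %d px (%.1f x %.1f um), %d-bit, range [%g, %g]\n",
    d[1], d[2], d[1] * x$calibration$pixel_size, d[2] * x$calibration$pixel_size,
    x$bit_depth, min(x$intensities), max(x$intensities)))
  if (!is.na(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' @export
dim.projection_image <- function(x) dim(x$intensities)

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a 3-D fluorescence stack to 2-D by taking, at every pixel, the
#' maximum over the z planes. The calibration is carried through unchanged.
#'
#' @param stack A 3-D array (rows x cols x planes) or a list of equally sized
#'   matrices, one per plane.
#' @param calibration A [pixel_calibration()].
#' @param ... Passed to [projection_image()] (`bit_depth`, `source_path`).
#' @return A [projection_image()].
#' @export
max_project <- function(stack, calibration, ...) {
  if (is.list(stack)) {
    if (length(stack) == 0L) stop("empty stack")
    dims <- lapply(stack, dim)
    if (any(vapply(dims, is.null, logical(1))) ||
        !all(vapply(dims, identical, logical(1), dims[[1]]))) {
      stop("inconsistent plane shapes")
    }
    arr <- array(unlist(stack, use.names = FALSE),
                 dim = c(dims[[1]], length(stack)))
  } else if (is.array(stack) && length(dim(stack)) == 3L) {
    if (dim(stack)[3] == 0L) stop("empty stack")
    arr <- stack
  } else if (is.matrix(stack)) {
    arr <- array(stack, dim = c(dim(stack), 1L))
  } else {
    stop("stack must be a 3-D array or a list of matrices")
  }
  proj <- apply(arr, c(1, 2), max)
  projection_image(proj, calibration, ...)
}

#' Load a grayscale image from disk
#'
#' Reads single- or multi-page grayscale TIFF and 8/16-bit grayscale PNG.
#' Multi-page TIFFs are max-projected. Intensities are preserved bit-exactly
#' in raw camera units; RGB inputs are rejected rather than silently
#' converted, because the pipeline assumes single-channel GFP images.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param calibration A [pixel_calibration()].
#' @return A [projection_image()].
#' @export
load_image <- function(path, calibration) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1)))) {
      stop("RGB/multi-channel input: convert to a single grayscale channel first")
    }
    bits <- if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L
    pages <- lapply(pages, function(p) {
      storage.mode(p) <- "double"
      p
    })
    max_project(pages, calibration, bit_depth = bits, source_path = path)
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    if (length(dim(raw)) > 2L) {
      stop("RGB/multi-channel input: convert to a single grayscale channel first")
    }
    # readPNG rescales to [0,1]; recover native integer levels
    v8 <- raw * 255
    if (max(abs(v8 - round(v8))) < 1e-9) {
      projection_image(round(v8), calibration, bit_depth = 8L, source_path = path)
    } else {
      projection_image(round(raw * 65535), calibration, bit_depth = 16L,
                       source_path = path)
    }
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Write a projection image to disk (TIFF or PNG)
#'
#' Inverse of [load_image()]; used by the phantom generator and overlay
#' writers. Values are written at the image's bit depth.
#'
#' @param img A [projection_image()].
#' @param path Output path; format from the extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "projection_image"))
  scale <- 2^img$bit_depth - 1
  m01 <- img$intensities / scale
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m01, path, bits.per.sample = img$bit_depth)
  } else if (ext == "png") {
    png::writePNG(m01, path)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}
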