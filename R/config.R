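#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one serialisable
#' object. All physical parameters are in micrometres and are converted to
#' pixels per image through the pixel calibration, which is what makes the
#' pipeline portable across cameras and objectives. Defaults are documented
#' with each field; change them only with reason.
#'
#' @param pixel_size Camera pixel size, um/pixel (required).
#' @param ... Named overrides of any default listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{contrast_lo_q, contrast_hi_q}{Quantiles (0.01, 0.999) of the global
#'     contrast stretch applied before any thresholding.}
#'   \item{soma_quantile}{Intensity quantile (0.995) defining the
#'     "brightest pixels" threshold for cell-body detection.}
#'   \item{soma_max_foreground}{Fraction (0.3) of foreground above which the
#'     soma threshold is declared to have failed (saturated image).}
#'   \item{soma_cluster_frac}{Components at least this fraction (0.2) of the
#'     largest bright component are counted into the soma cluster.}
#'   \item{circularity_min}{An object counts as "circular" above this
#'     circularity (0.6).}
#'   \item{elongation_min, dendrite_angle_max}{An object is "dendrite-like"
#'     when major/minor axis > 4 and its axis is within 30 degrees of
#'     vertical.}
#'   \item{min_object_height_frac}{Border-touching clutter shorter than this
#'     fraction (0.3) of the tallest object is removed during cropping.}
#'   \item{crop_margin_um}{Physical padding (2 um) around the dendrite
#'     bounding box.}
#'   \item{dendrite_width_um}{Expected dendrite width (0.75 um); sets the
#'     break-probe half-width and the bleb erosion length.}
#'   \item{bg_radius_um}{Radius (5 um) of the opening used as the
#'     rolling-ball style background estimate.}
#'   \item{erode_len_um}{Horizontal erosion length (2 x dendrite width) that
#'     removes thin vertical dendrites before bleb detection.}
#'   \item{seed_min_px}{Seeds smaller than this many enhanced pixels (2) are
#'     discarded as noise.}
#'   \item{min_feature_area_um2}{Refined features smaller than this area
#'     (0.5 um^2, about a dendrite cross-section) are not blebs and are
#'     dropped.}
#'   \item{cv_iters}{Chan-Vese iteration budget (50).}
#'   \item{noise_k}{Multiplier (1.0) of the noise estimate added to the Otsu
#'     level for bleb thresholding.}
#'   \item{min_sep_um}{Minimum lateral separation (1.5 um) between per-row
#'     intensity maxima.}
#'   \item{prominence_k}{Peaks must exceed background by this multiple (2) of
#'     the noise estimate.}
#'   \item{closing_gap_um}{Vertical closing length (4 um) bridging small gaps
#'     between row maxima.}
#'   \item{smooth_window_um}{Moving-average window (3 um) for track
#'     smoothing.}
#'   \item{track_memory_rows}{Row memory (25) of the exponential running
#'     average used to bin points into dendrite indices.}
#'   \item{new_track_k}{A point opens a new dendrite index when farther than
#'     this multiple (3) of min_sep from every running average.}
#'   \item{min_segment_rows}{Skeleton segments supported by fewer rows (3)
#'     are discarded as noise.}
#'   \item{track_open_min_rows}{Only segments with at least this many rows
#'     (5) may open a new dendrite index.}
#'   \item{match_radius_um}{Maximum centroid-to-track distance (3 um) for
#'     bleb-to-dendrite matching.}
#'   \item{cat_remaining_hi, cat_remaining_lo, cat_bleb_cut}{Categorical
#'     score boundaries: >0.85 remaining, <=0.50 remaining, 5 blebs.}
#'   \item{overlap_frac_max}{QC: flag the image when two tracks coincide for
#'     more than this fraction (0.2) of rows.}
#' }
#' @return An object of class `"cep_config"` (a named list).
#' @export
cep_config <- function(pixel_size, ...) {
  cfg <- list(
    pixel_size = pixel_size,
    contrast_lo_q = 0.01, contrast_hi_q = 0.999,
    soma_quantile = 0.995, soma_max_foreground = 0.30, soma_cluster_frac = 0.2,
    circularity_min = 0.6, elongation_min = 4, dendrite_angle_max = 30,
    min_object_height_frac = 0.3, crop_margin_um = 2,
    dendrite_width_um = 0.75, bg_radius_um = 5,
    erode_len_um = 1.5, seed_min_px = 2L, cv_iters = 50L, noise_k = 1.0,
    min_feature_area_um2 = 0.5,
    min_sep_um = 1.5, prominence_k = 2, closing_gap_um = 4,
    smooth_window_um = 3, track_memory_rows = 25, new_track_k = 3,
    min_segment_rows = 3L, track_open_min_rows = 5L,
    match_radius_um = 3,
    cat_remaining_hi = 0.85, cat_remaining_lo = 0.50, cat_bleb_cut = 5,
    overlap_frac_max = 0.20,
    version = as.character(utils::packageVersion("cepscore"))
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg$calibration <- pixel_calibration(cfg$pixel_size)
  structure(cfg, class = "cep_config")
}

#' @export
print.cep_config <- function(x, ...) {
  cat("cepscore run configuration (", x$version, "), pixel size ",
      x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

#' Serialise / restore a run configuration
#'
#' The JSON side-car written next to every metric report records the full
#' configuration (pixel size, all thresholds, software version) so a run can
#' be reproduced exactly.
#'
#' @param config A [cep_config()].
#' @param path Output (input) JSON path.
#' @return `config_to_json`: `path` invisibly; `config_from_json`: a
#'   [cep_config()].
#' @export
config_to_json <- function(config, path) {
  x <- unclass(config)
  x$calibration <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ps <- x$pixel_size
  x$pixel_size <- NULL
  x$version <- NULL
  do.call(cep_config, c(list(pixel_size = ps), x))
}
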