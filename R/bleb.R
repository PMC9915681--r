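# Bleb ("beads on a string") feature detection on the cropped dendrite
# image: local contrast adjustment, 4x upsampling, background subtraction,
# noise-adaptive global thresholding, horizontal erosion to delete the thin
# vertical dendrites, and Chan-Vese refinement of the surviving seeds.

# robust background noise estimate: scaled MAD of the below-Otsu pixels of a
# [0,1] image
estimate_noise <- function(m01) {
  thr <- EBImage::otsu(as_ebi(m01), range = c(0, 1))
  bg <- m01[m01 <= thr]
  if (length(bg) < 16L) bg <- as.vector(m01)
  1.4826 * stats::mad(bg, constant = 1)
}

#' Enhance a dendrite crop for feature detection
#'
#' Applies a local (CLAHE-style) contrast adjustment whose clip limit shrinks
#' as the background noise grows (noisy images must not have their noise
#' amplified), upsamples 4x with intensity interpolation to gain pixels for
#' the morphological steps, and subtracts a rolling-ball style background --
#' the morphological opening with a disk of `bg_radius_um` -- to flatten
#' uneven illumination. The opening is computed at the original scale and
#' upsampled, which gives the same large-scale background estimate at a
#' fraction of the cost.
#'
#' @param crop A `"dendrite_crop"`.
#' @param config A [cep_config()].
#' @return An object of class `"enhanced_image"`: `intensities` (4x matrix,
#'   `[0,1]`), `local_contrast` (original-scale contrast-adjusted matrix, the
#'   tracking input), `scale_factor` (4), `noise_estimate`, `crop`.
#' @export
enhance_crop <- function(crop, config) {
  stopifnot(inherits(crop, "dendrite_crop"))
  m <- crop$image$intensities
  scale <- 2^crop$image$bit_depth - 1
  m01 <- m / scale
  noise <- estimate_noise(m01)
  lc <- local_contrast(m01, noise)
  up <- from_ebi(EBImage::resize(as_ebi(lc), w = ncol(lc) * 4L,
                                 h = nrow(lc) * 4L, filter = "bilinear"))
  r_px <- to_pixels(config$bg_radius_um, config$calibration)
  bg <- ebi_morph(lc, disc_brush(r_px), "opening")
  bg_up <- from_ebi(EBImage::resize(as_ebi(bg), w = ncol(lc) * 4L,
                                    h = nrow(lc) * 4L, filter = "bilinear"))
  enh <- pmax(up - bg_up, 0)
  raw_up <- from_ebi(EBImage::resize(as_ebi(m01), w = ncol(m01) * 4L,
                                     h = nrow(m01) * 4L,
                                     filter = "bilinear"))
  structure(
    list(intensities = enh, raw_intensities = raw_up, local_contrast = lc,
         scale_factor = 4L, noise_estimate = noise, crop = crop),
    class = "enhanced_image")
}

# CLAHE with a clip limit mapped down as the noise estimate rises; falls back
# to the global stretch on degenerate (tiny or flat) inputs
local_contrast <- function(m01, noise) {
  if (max(m01) - min(m01) < 1e-9) return(m01)
  limit <- max(1.2, 4 / (1 + noise / 0.02))
  nx <- max(2L, min(8L, ncol(m01) %/% 24L))
  ny <- max(2L, min(8L, nrow(m01) %/% 24L))
  out <- tryCatch(
    from_ebi(EBImage::clahe(as_ebi(m01), nx = nx, ny = ny, limit = limit)),
    error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    rng <- range(m01)
    out <- (m01 - rng[1]) / (rng[2] - rng[1])
  }
  pmin(pmax(out, 0), 1)
}

#' Segment candidate bleb seeds
#'
#' Global threshold at the Otsu level plus `noise_k` times the noise estimate
#' (noisier images get a higher threshold), then erosion with a horizontal
#' line of `erode_len_um` (in enhanced pixels): dendrites are thinner than
#' blebs, so the thin vertical strands vanish while clusters wider than the
#' line survive as seeds.
#'
#' @param enh An [enhance_crop()] result.
#' @param config A [cep_config()].
#' @return List: `seeds` (label matrix of surviving seed components),
#'   `pre_erosion` (label matrix of the thresholded mask before erosion, the
#'   Chan-Vese fallback), `threshold`, `qc_warning` (character, possibly
#'   empty).
#' @export
segment_candidates <- function(enh, config) {
  stopifnot(inherits(enh, "enhanced_image"))
  E <- enh$intensities
  thr <- min(0.95, EBImage::otsu(as_ebi(E), range = c(0, 1)) +
               config$noise_k * enh$noise_estimate)
  mask <- E > thr
  len <- to_pixels(config$erode_len_um, config$calibration) * enh$scale_factor
  qc <- character(0)
  dw <- to_pixels(config$dendrite_width_um, config$calibration) *
    enh$scale_factor
  if (len <= dw) {
    qc <- paste("erosion length does not exceed the expected dendrite width;",
                "dendrites may be reported as features")
  }
  eroded <- ebi_morph(mask * 1.0, line_brush(len, "horizontal"), "erode") > 0.5
  seeds <- label_mask(eroded)
  if (max(seeds) > 0) {
    areas <- tabulate(seeds[seeds > 0])
    drop <- which(areas < config$seed_min_px)
    if (length(drop)) seeds[seeds %in% drop] <- 0L
    seeds <- label_mask(seeds > 0)
  }
  list(seeds = seeds, pre_erosion = label_mask(mask), threshold = thr,
       qc_warning = qc)
}

#' Refine bleb seeds with Chan-Vese active contours
#'
#' Horizontal erosion leaves jagged, horizontally biased shapes, so each seed
#' is refined by a two-phase Chan-Vese segmentation run on a local window
#' (3x the seed bounding box) for `cv_iters` iterations, initialised from the
#' seed. The contour evolves on the upsampled raw-intensity field rather
#' than the equalised one: local equalisation pulls dendrite brightness up
#' to bleb level, which would let the contour leak along the strand, whereas
#' in raw units a bleb genuinely outshines its dendrite. A collapsed contour
#' falls back to the seed's pre-erosion connected component. Refined masks
#' that touch are merged into single features.
#'
#' @param enh An [enhance_crop()] result.
#' @param cand A [segment_candidates()] result.
#' @param config A [cep_config()].
#' @return Label matrix of refined feature masks in enhanced coordinates.
#' @export
refine_features <- function(enh, cand, config) {
  E <- if (!is.null(enh$raw_intensities)) enh$raw_intensities
       else enh$intensities
  seeds <- cand$seeds
  nlab <- max(seeds)
  canvas <- matrix(FALSE, nrow(E), ncol(E))
  if (nlab < 1) return(label_mask(canvas))
  props <- region_props(seeds)
  for (i in seq_len(nrow(props))) {
    pr <- props[i, ]
    hh <- pr$rmax - pr$rmin + 1L; ww <- pr$cmax - pr$cmin + 1L
    r1 <- max(1L, pr$rmin - hh); r2 <- min(nrow(E), pr$rmax + hh)
    c1 <- max(1L, pr$cmin - ww); c2 <- min(ncol(E), pr$cmax + ww)
    win <- E[r1:r2, c1:c2, drop = FALSE]
    init <- seeds[r1:r2, c1:c2, drop = FALSE] == pr$label
    cv <- chan_vese(win, init, iters = config$cv_iters,
                    smooth_sigma = max(1, enh$scale_factor / 4))
    ok <- FALSE
    if (!is.null(cv)) {
      # keep only the refined component(s) overlapping the seed
      lab <- label_mask(cv)
      hit <- unique(lab[init & lab > 0])
      if (length(hit)) {
        canvas[r1:r2, c1:c2] <- canvas[r1:r2, c1:c2] |
          matrix(lab %in% hit, nrow(win), ncol(win))
        ok <- TRUE
      }
    }
    if (!ok) {
      # contour collapse: fall back to the pre-erosion component
      pe <- cand$pre_erosion
      hit <- unique(pe[seeds == pr$label & pe > 0])
      if (length(hit)) canvas <- canvas | matrix(pe %in% hit, nrow(E), ncol(E))
      else canvas[seeds == pr$label] <- TRUE
    }
  }
  label_mask(canvas)
}

#' Measure bleb features
#'
#' Computes the shape and intensity descriptors of each refined feature:
#' area (um^2), circularity (4 pi A / P^2), extent (area over bounding-box
#' area: 1 for a filled rectangle, near 0 for a cross), eccentricity, min and
#' max caliper (Feret) diameters (um), and the mean intensity of the original
#' unenhanced crop under the feature footprint. Physical units use
#' `pixel_size / scale_factor` per enhanced pixel. Features smaller than
#' `min_feature_area_um2` (about one dendrite cross-section) are discarded:
#' a bleb by definition protrudes beyond the dendrite. Dendrite assignment
#' and arc positions are filled in later by [match_features()].
#'
#' @param masks Label matrix from [refine_features()] (enhanced coords).
#' @param enh The [enhance_crop()] result the masks came from.
#' @param config A [cep_config()].
#' @return A data frame of class `"bleb_features"`, one row per feature.
#' @export
measure_features <- function(masks, enh, config) {
  crop <- enh$crop
  sf <- enh$scale_factor
  p_enh <- config$pixel_size / sf
  props <- region_props(masks)
  n <- nrow(props)
  raw <- crop$image$intensities
  mean_int <- numeric(n)
  if (n) {
    idx_all <- which(masks > 0)
    lab_all <- masks[idx_all]
    rr <- (idx_all - 1L) %% nrow(masks) + 1L
    cc <- (idx_all - 1L) %/% nrow(masks) + 1L
    # downscale the footprint to crop pixels
    r0 <- pmin(nrow(raw), (rr - 1L) %/% sf + 1L)
    c0 <- pmin(ncol(raw), (cc - 1L) %/% sf + 1L)
    for (l in seq_len(n)) {
      sel <- lab_all == props$label[l]
      pix <- unique((c0[sel] - 1L) * nrow(raw) + r0[sel])
      mean_int[l] <- mean(raw[pix])
    }
  }
  # border-touching detections are unreliable (cut off by the crop, or the
  # widening stalk glow at the cell-body edge) and are removed, as is
  # anything smaller than a dendrite cross-section
  margin <- 2L
  on_border <- props$rmin <= margin | props$cmin <= margin |
    props$rmax >= nrow(masks) - margin + 1L |
    props$cmax >= ncol(masks) - margin + 1L
  keep <- !on_border & props$area * p_enh^2 >= config$min_feature_area_um2
  props <- props[keep, , drop = FALSE]
  mean_int <- mean_int[keep]
  n <- nrow(props)
  out <- data.frame(
    feature = seq_len(n),
    centroid_row = (props$centroid_row - 0.5) / sf + 0.5,
    centroid_col = (props$centroid_col - 0.5) / sf + 0.5,
    area_um2 = props$area * p_enh^2,
    circularity = props$circularity,
    extent = props$extent,
    eccentricity = props$eccentricity,
    min_caliper_um = props$min_caliper * p_enh,
    max_caliper_um = props$max_caliper * p_enh,
    mean_intensity = mean_int,
    dendrite_index = rep(NA_integer_, n),
    norm_location = rep(NA_real_, n),
    distance_from_cell_body_um = rep(NA_real_, n))
  class(out) <- c("bleb_features", "data.frame")
  out
}

#' Detect and measure blebs on a dendrite crop
#'
#' Convenience wrapper chaining [enhance_crop()], [segment_candidates()],
#' [refine_features()] and [measure_features()].
#'
#' @param crop A `"dendrite_crop"`.
#' @param config A [cep_config()].
#' @return List: `features` (a `"bleb_features"` frame), `enhanced`, `masks`,
#'   `qc_warning`.
#' @export
detect_blebs <- function(crop, config) {
  enh <- enhance_crop(crop, config)
  cand <- segment_candidates(enh, config)
  masks <- refine_features(enh, cand, config)
  list(features = measure_features(masks, enh, config), enhanced = enh,
       masks = masks, qc_warning = cand$qc_warning)
}
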