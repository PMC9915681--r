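# Dendrite-region detection: locate the cell bodies, rotate the worm so the
# dendrites run vertically, split at the soma bounding box, pick the half that
# contains the dendrites, and crop away border clutter.

# global linear contrast stretch of the (lo_q, hi_q) quantile range to [0, 1]
contrast_adjust <- function(m, config) {
  q <- stats::quantile(m, c(config$contrast_lo_q, config$contrast_hi_q),
                       names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(m), ncol(m)))
  pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Detect the CEP cell bodies
#'
#' The four cell bodies are usually the brightest objects in the frame, so a
#' high-quantile threshold on the contrast-adjusted image isolates them. All
#' bright components within `soma_cluster_frac` of the largest define the soma
#' cluster; its union bounding box and intensity-weighted centroid anchor the
#' split step. The principal angle of the full above-background foreground
#' (soma + dendrite complex, from second-order central moments) estimates how
#' far the worm is from vertical.
#'
#' @param img A [projection_image()].
#' @param config A [cep_config()].
#' @return An object of class `"cell_body_detection"`: `mask`, `bbox`
#'   (`rmin, rmax, cmin, cmax`, half-open), `centroid` (`row, col`),
#'   `principal_angle` (degrees from vertical), `threshold`.
#' @export
detect_cell_bodies <- function(img, config) {
  m <- img$intensities
  if (max(m) - min(m) < .Machine$double.eps * max(1, max(m))) {
    stop("no cell body found")
  }
  adj <- contrast_adjust(m, config)
  thr <- stats::quantile(adj, config$soma_quantile, names = FALSE)
  mask <- adj >= thr & adj > 0
  if (mean(mask) > config$soma_max_foreground) {
    stop("image saturated or threshold failure")
  }
  if (!any(mask)) stop("no cell body found")
  labels <- label_mask(mask)
  props <- region_props(labels)
  keep <- props$label[props$area >= config$soma_cluster_frac * max(props$area)]
  cluster <- matrix(labels %in% keep, nrow(m), ncol(m))
  idx <- which(cluster)
  rr <- (idx - 1L) %% nrow(m) + 1L
  cc <- (idx - 1L) %/% nrow(m) + 1L
  w <- adj[idx]
  centroid <- c(sum(rr * w) / sum(w), sum(cc * w) / sum(w))
  bbox <- c(min(rr), max(rr) + 1L, min(cc), max(cc) + 1L)
  # principal axis of the soma + dendrite complex: intensity-weighted central
  # moments with the background suppressed, so the dim dendrites still steer
  # the axis rather than only the bright somas
  angle <- principal_angle_weighted(adj)
  structure(
    list(mask = cluster, bbox = bbox, centroid = centroid,
         principal_angle = angle, threshold = thr),
    class = "cell_body_detection")
}

#' Rotate an image so the dendrites are vertical
#'
#' Rotates by the detection's principal angle (intensity interpolation,
#' padding with the background median) so the dendrite axis is within a few
#' degrees of vertical, then re-detects the cell bodies in the rotated frame.
#'
#' @param img A [projection_image()].
#' @param det A [detect_cell_bodies()] result.
#' @param config A [cep_config()].
#' @return List: `image` (rotated [projection_image()]), `angle` (degrees
#'   applied), `detection` (re-detected cell bodies).
#' @export
orient_vertical <- function(img, det, config) {
  angle <- det$principal_angle
  # tilts below the angle estimator's own noise floor (about 2 degrees on
  # images with asymmetric blebbing) are not corrected: interpolating the
  # whole frame would blur it for no geometric gain
  if (abs(angle) < 2) {
    return(list(image = img, angle = 0, detection = det))
  }
  bg <- stats::median(img$intensities)
  scale <- 2^img$bit_depth - 1
  rot <- EBImage::rotate(as_ebi(img$intensities / scale), angle = angle,
                         bg.col = bg / scale)
  m <- pmin(pmax(from_ebi(rot), 0), 1) * scale
  out <- projection_image(m, img$calibration, bit_depth = img$bit_depth,
                          source_path = img$source_path)
  list(image = out, angle = angle, detection = detect_cell_bodies(out, config))
}

# angle (degrees from vertical, in (-90, 90]) of the weighted principal axis
principal_angle_weighted <- function(adj) {
  w <- pmax(adj - (stats::median(adj) + 2 * estimate_noise(adj)), 0)
  if (sum(w) <= 0) return(0)
  idx <- which(w > 0)
  rr <- (idx - 1L) %% nrow(adj) + 1L
  cc <- (idx - 1L) %/% nrow(adj) + 1L
  ww <- w[idx] / sum(w[idx])
  mr <- sum(ww * rr); mc <- sum(ww * cc)
  mrr <- sum(ww * (rr - mr)^2); mcc <- sum(ww * (cc - mc)^2)
  mrc <- sum(ww * (rr - mr) * (cc - mc))
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  if (abs(mrc) < 1e-9) return(if (mrr >= mcc) 0 else 90)
  v <- c(l1 - mcc, mrc)
  a <- atan2(v[2], v[1]) * 180 / pi
  if (a > 90) a - 180 else if (a <= -90) a + 180 else a
}

# otsu binarisation of the contrast-adjusted matrix; the threshold is
# floored at the background noise level so that nearly-empty fields (e.g.
# heavily degenerated dendrites) do not binarise their noise
otsu_mask <- function(m, config) {
  adj <- contrast_adjust(m, config)
  thr <- max(EBImage::otsu(as_ebi(adj), range = c(0, 1)),
             stats::median(adj) + 3 * estimate_noise(adj))
  adj > thr
}

# per-object classification used for half selection and border cleanup
classify_objects <- function(props, config) {
  circ <- props$circularity > config$circularity_min
  dend <- props$major_axis > config$elongation_min * pmax(props$minor_axis, 0.5) &
    abs(props$angle_from_vertical) < config$dendrite_angle_max
  list(circular = circ, dendrite_like = dend & !circ)
}

#' Split at the cell bodies and select the dendrite half
#'
#' Splits the rotated image horizontally at the soma bounding box, binarises
#' both halves with an Otsu threshold, and measures each connected object
#' (orientation, axis lengths, circularity, area). Cell bodies are circular
#' while dendrites are elongated and near-vertical, so the half with more
#' dendrite-like and fewer circular objects is chosen; ties go to the half
#' with the greater summed major-axis length.
#'
#' @param img Rotated [projection_image()].
#' @param det [detect_cell_bodies()] result for `img`.
#' @param config A [cep_config()].
#' @return List: `halves` (two lists with `intensities`, `row_offset`,
#'   `soma_side`), `chosen` (1 or 2), `scores` (per-half object tallies).
#' @export
split_and_select <- function(img, det, config) {
  m <- img$intensities
  r0 <- det$bbox[1]; r1 <- det$bbox[2]   # soma band rows [r0, r1)
  if (r0 <= 1L || r1 > nrow(m)) {
    r0 <- max(2L, r0); r1 <- min(nrow(m), r1)
  }
  halves <- list(
    list(intensities = m[seq_len(r0 - 1L), , drop = FALSE],
         row_offset = 0L, soma_side = "bottom"),
    list(intensities = m[r1:nrow(m), , drop = FALSE],
         row_offset = r1 - 1L, soma_side = "top"))
  score_half <- function(h) {
    if (nrow(h$intensities) < 3L) {
      return(list(n_dendrite = -Inf, n_circular = Inf, major_sum = 0,
                  props = NULL))
    }
    mask <- otsu_mask(h$intensities, config)
    props <- region_props(label_mask(mask))
    props <- props[props$area >= 4, , drop = FALSE]
    cls <- classify_objects(props, config)
    list(n_dendrite = sum(cls$dendrite_like), n_circular = sum(cls$circular),
         major_sum = sum(props$major_axis[cls$dendrite_like]), props = props)
  }
  scores <- lapply(halves, score_half)
  any_fg <- vapply(scores, function(s) !is.null(s$props) && nrow(s$props) > 0,
                   logical(1))
  if (!any(any_fg)) stop("no dendrites detected")
  key <- vapply(seq_along(scores), function(i) {
    s <- scores[[i]]
    if (!any_fg[i]) return(-Inf)
    s$n_dendrite * 1e6 - s$n_circular * 1e3 + s$major_sum
  }, numeric(1))
  chosen <- which.max(key)
  list(halves = halves, chosen = chosen, scores = scores)
}

#' Crop the selected half down to the dendrite region
#'
#' Removes clutter from the dendrite half: objects that are not dendrite-like
#' are dropped when they touch any border (this excludes residual soma pixels
#' along the split line and edge artefacts), as is anything shorter than
#' `min_object_height_frac` of the tallest object. The tight bounding box of
#' what remains, padded by `crop_margin_um`, defines the crop. The crop is
#' flipped if needed so the cell-body side is always the bottom row.
#'
#' @param split A [split_and_select()] result.
#' @param det [detect_cell_bodies()] result for the rotated image.
#' @param config A [cep_config()].
#' @param angle Rotation (degrees) that produced the rotated frame.
#' @param img The rotated [projection_image()] (for calibration/bit depth).
#' @return An object of class `"dendrite_crop"`: `image`
#'   ([projection_image()] of the crop), `mask` (binary dendrite mask),
#'   `transform` (rotation angle, row/col offsets, flipped flag),
#'   `cell_body_side` (always "bottom" after normalisation; original side in
#'   the transform).
#' @export
crop_dendrite_region <- function(split, det, config, angle, img) {
  h <- split$halves[[split$chosen]]
  m <- h$intensities
  mask <- otsu_mask(m, config)
  labels <- label_mask(mask)
  props <- region_props(labels)
  props <- props[props$area >= 4, , drop = FALSE]
  if (!nrow(props)) stop("no dendrites detected")
  cls <- classify_objects(props, config)
  heights <- props$rmax - props$rmin + 1L
  touches <- props$rmin <= 1L | props$rmax >= nrow(m) |
    props$cmin <= 1L | props$cmax >= ncol(m)
  keep <- cls$dendrite_like |
    (!touches & heights >= config$min_object_height_frac * max(heights))
  keep <- keep & heights >= config$min_object_height_frac * max(heights)
  if (!any(keep)) keep <- heights == max(heights)
  kept_mask <- matrix(labels %in% props$label[keep], nrow(m), ncol(m))
  idx <- which(kept_mask)
  rr <- range((idx - 1L) %% nrow(m) + 1L)
  cc <- range((idx - 1L) %/% nrow(m) + 1L)
  pad <- to_pixels(config$crop_margin_um, config$calibration)
  r <- c(max(1L, rr[1] - pad), min(nrow(m), rr[2] + pad))
  c2 <- c(max(1L, cc[1] - pad), min(ncol(m), cc[2] + pad))
  crop_m <- m[r[1]:r[2], c2[1]:c2[2], drop = FALSE]
  crop_mask <- kept_mask[r[1]:r[2], c2[1]:c2[2], drop = FALSE]
  flipped <- h$soma_side == "top"
  if (flipped) {
    crop_m <- crop_m[rev(seq_len(nrow(crop_m))), , drop = FALSE]
    crop_mask <- crop_mask[rev(seq_len(nrow(crop_mask))), , drop = FALSE]
  }
  structure(
    list(
      image = projection_image(crop_m, img$calibration,
                               bit_depth = img$bit_depth,
                               source_path = img$source_path),
      mask = crop_mask,
      transform = list(rotation_angle = angle,
                       row_offset = h$row_offset + r[1] - 1L,
                       col_offset = c2[1] - 1L, flipped = flipped,
                       original_soma_side = h$soma_side),
      cell_body_side = "bottom"),
    class = "dendrite_crop")
}

#' @export
print.dendrite_crop <- function(x, ...) {
  d <- dim(x$image$intensities)
  cat(sprintf(
    "Dendrite crop: %d x %d px, rotation %.1f deg, soma side %s%s\n",
    d[1], d[2], x$transform$rotation_angle, x$transform$original_soma_side,
    if (x$transform$flipped) " (flipped to bottom)" else ""))
  invisible(x)
}

#' Full dendrite-region detection
#'
#' Convenience wrapper chaining [detect_cell_bodies()], [orient_vertical()],
#' [split_and_select()] and [crop_dendrite_region()].
#'
#' @param img A [projection_image()].
#' @param config A [cep_config()].
#' @return A `"dendrite_crop"`.
#' @export
detect_dendrite_region <- function(img, config) {
  det <- detect_cell_bodies(img, config)
  ori <- orient_vertical(img, det, config)
  split <- split_and_select(ori$image, ori$detection, config)
  crop_dendrite_region(split, ori$detection, config, ori$angle, ori$image)
}
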