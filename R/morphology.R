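# Internal morphology / region-measurement helpers shared across modules.
#
# Convention: images are base-R numeric matrices indexed (row, col) with row 1
# at the top. EBImage stores images (x, y) = (col, row), so every call into
# EBImage goes through as_ebi()/from_ebi() which transpose.

as_ebi <- function(m) EBImage::Image(t(m))

from_ebi <- function(e) t(EBImage::imageData(e))

# grayscale erosion/dilation/opening/closing on (row, col) matrices
ebi_morph <- function(m, brush, op = c("erode", "dilate", "opening", "closing")) {
  op <- match.arg(op)
  f <- switch(op, erode = EBImage::erode, dilate = EBImage::dilate,
              opening = EBImage::opening, closing = EBImage::closing)
  from_ebi(f(as_ebi(m), brush))
}

# line brush along image rows (vertical) or cols (horizontal), odd length
line_brush <- function(len_px, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  len_px <- max(1L, as.integer(len_px))
  len_px <- len_px + (len_px %% 2L == 0L)
  # in EBImage coords x = our col: angle 0 is along cols (horizontal)
  EBImage::makeBrush(len_px, shape = "line",
                     angle = if (direction == "horizontal") 0 else 90)
}

disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * max(1L, as.integer(radius_px)) + 1L, shape = "disc")
}

# connected-component labelling (8-connectivity), (row, col) matrix in/out
label_mask <- function(mask) {
  storage.mode(mask) <- "double"
  from_ebi(EBImage::bwlabel(as_ebi(mask)))
}

# Kulpa chain-length perimeter estimate from EBImage oriented contours.
# Weights 0.948 (axial step) and 1.340 (diagonal step) give digital-disk
# perimeters within ~2% of 2*pi*r.
kulpa_perimeter <- function(labels) {
  oc <- EBImage::ocontour(as_ebi(labels))
  vapply(seq_along(oc), function(i) {
    pts <- oc[[i]]
    n <- nrow(pts)
    if (is.null(n) || n < 2L) return(1.0)
    d <- pts - pts[c(2:n, 1L), , drop = FALSE]
    steps <- abs(d[, 1]) + abs(d[, 2])
    sum(ifelse(steps >= 2, 1.340, 0.948) * (steps > 0))
  }, numeric(1))
}

# Feret (caliper) diameters of a pixel set: min/max over orientations of the
# projected extent (+1 px for the pixel footprint). coords = cbind(row, col).
feret_calipers <- function(coords, n_angles = 90L) {
  th <- seq(0, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  proj_r <- outer(coords[, 1], cos(th)) + outer(coords[, 2], sin(th))
  widths <- apply(proj_r, 2, function(v) diff(range(v))) + 1
  c(min = min(widths), max = max(widths))
}

# regionprops-style table for a label matrix. Intensity stats are taken from
# `intensity` (same shape) when given. Orientation is the angle (degrees) of
# the major axis measured from the vertical (row) axis, in (-90, 90].
region_props <- function(labels, intensity = NULL) {
  nlab <- max(labels)
  empty <- data.frame(
    label = integer(0), area = numeric(0), centroid_row = numeric(0),
    centroid_col = numeric(0), rmin = integer(0), rmax = integer(0),
    cmin = integer(0), cmax = integer(0), major_axis = numeric(0),
    minor_axis = numeric(0), eccentricity = numeric(0),
    angle_from_vertical = numeric(0), perimeter = numeric(0),
    circularity = numeric(0), extent = numeric(0),
    min_caliper = numeric(0), max_caliper = numeric(0),
    mean_intensity = numeric(0))
  if (nlab < 1) return(empty)
  perim <- kulpa_perimeter(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  out <- lapply(seq_len(nlab), function(l) {
    sel <- lab == l
    if (!any(sel)) return(NULL)
    r <- rr[sel]; c <- cc[sel]
    n <- length(r)
    mr <- mean(r); mc <- mean(c)
    # central second moments with the 1/12 pixel-footprint correction
    mrr <- mean((r - mr)^2) + 1 / 12
    mcc <- mean((c - mc)^2) + 1 / 12
    mrc <- mean((r - mr) * (c - mc))
    common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
    l1 <- (mrr + mcc + common) / 2
    l2 <- (mrr + mcc - common) / 2
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(max(l2, 0))
    ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
    # eigenvector of the larger eigenvalue in (row, col) coords
    ang <- if (abs(mrc) < 1e-12 && mrr >= mcc) 0
           else if (abs(mrc) < 1e-12) 90
           else {
             v <- c(l1 - mcc, mrc)     # (row, col) direction of major axis
             a <- atan2(v[2], v[1]) * 180 / pi
             if (a > 90) a - 180 else if (a <= -90) a + 180 else a
           }
    bbox <- c(min(r), max(r), min(c), max(c))
    cal <- feret_calipers(cbind(r, c))
    p <- perim[l]
    data.frame(
      label = l, area = n, centroid_row = mr, centroid_col = mc,
      rmin = bbox[1], rmax = bbox[2], cmin = bbox[3], cmax = bbox[4],
      major_axis = major, minor_axis = minor, eccentricity = ecc,
      angle_from_vertical = ang, perimeter = p,
      circularity = 4 * pi * n / p^2,
      extent = n / ((bbox[2] - bbox[1] + 1) * (bbox[4] - bbox[3] + 1)),
      min_caliper = cal[["min"]], max_caliper = cal[["max"]],
      mean_intensity = if (is.null(intensity)) NA_real_
                       else mean(intensity[idx[sel]]))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Two-phase Chan-Vese segmentation on a small window, initialised from a seed
# mask. Alternates the optimal binary partition (each pixel joins the phase
# whose mean it is closer to, with an area-penalty margin `nu` that biases
# ties toward background and stops the inside mean from creeping down onto
# adjacent dimmer structure) with a Gaussian smoothing of the indicator (the
# curvature-regularisation surrogate). Returns a logical matrix, or NULL if
# the contour collapses.
chan_vese <- function(img, init, iters = 50L, smooth_sigma = 1.0,
                      nu = 0.15) {
  phi <- init > 0
  if (!any(phi) || all(phi)) return(NULL)
  for (i in seq_len(iters)) {
    c1 <- mean(img[phi]); c2 <- mean(img[!phi])
    if (!is.finite(c1) || !is.finite(c2) || abs(c1 - c2) < 1e-9) return(NULL)
    cls <- img >= (c1 + c2) / 2 + nu * abs(c1 - c2)
    # gblur needs the image to be at least as large as its kernel
    ksize <- 2L * ceiling(3 * smooth_sigma) + 1L
    sm <- if (all(dim(cls) >= ksize)) {
      from_ebi(EBImage::gblur(as_ebi(cls * 1.0), sigma = smooth_sigma))
    } else cls * 1.0
    new_phi <- sm > 0.5
    if (!any(new_phi) || all(new_phi)) return(NULL)
    if (identical(new_phi, phi)) break
    phi <- new_phi
  }
  phi
}

# Per-row local maxima of a 1-D profile: strictly-greater-than-neighbours
# peaks (plateau centres), above `floor`, greedily thinned to a minimum
# separation, at most `k` kept by decreasing height.
profile_peaks <- function(v, floor, min_dist, k) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  d <- diff(v)
  s <- sign(d)
  # propagate plateau slopes so flat tops count once
  for (i in seq_len(n - 1L)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  cand <- which(diff(s) < 0) + 1L
  cand <- cand[v[cand] >= floor]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(kept - p) >= min_dist)) {
      kept <- c(kept, p)
      if (length(kept) >= k) break
    }
  }
  sort(kept)
}

# deterministic RNG scope
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
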