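# Dendrite tracking: per-row local intensity maxima, vertical morphological
# closing, skeletonisation, running-average binning into at most four
# dendrite indices, de-duplication, interpolation and smoothing.

#' Per-row local intensity maxima
#'
#' For every pixel row of the local-contrast crop image, finds up to `k`
#' local maxima of the intensity profile that exceed a noise-based prominence
#' floor (background median plus `prominence_k` times the noise estimate) and
#' are mutually at least `min_sep_um` apart; when more qualify, the `k` most
#' intense are kept. Rows inside breaks naturally yield fewer points.
#'
#' The floor is computed on the local-contrast image itself (not the raw
#' crop), since adaptive equalisation amplifies background noise: it is the
#' larger of the background median plus `prominence_k` noise deviations and
#' the image's Otsu level.
#'
#' @param lc Local-contrast matrix (`[0,1]`, original crop scale).
#' @param config A [cep_config()].
#' @param k Maximum points per row (default 4).
#' @param noise Unused legacy argument kept for call compatibility; the
#'   floor always derives from `lc`.
#' @return Logical point mask, same shape as `lc`.
#' @export
rowwise_maxima <- function(lc, config, k = 4L, noise = NULL) {
  noise_lc <- estimate_noise(lc)
  floor_lvl <- max(stats::median(lc) + config$prominence_k * noise_lc,
                   EBImage::otsu(as_ebi(lc), range = c(0, 1)))
  min_dist <- to_pixels(config$min_sep_um, config$calibration)
  pts <- matrix(FALSE, nrow(lc), ncol(lc))
  for (r in seq_len(nrow(lc))) {
    pk <- profile_peaks(lc[r, ], floor_lvl, min_dist, k)
    if (length(pk)) pts[r, pk] <- TRUE
  }
  pts
}

#' Close point mask vertically and skeletonise
#'
#' A small isotropic dilation first restores 8-connectivity across the
#' pixel-level lateral jitter of the per-row maxima; a morphological closing
#' with a vertical line of `closing_gap_um` then bridges small vertical gaps
#' (rows where a maximum was missed), connecting each dendrite to itself.
#' Each closed component is reduced back to a one-pixel-wide skeleton: the
#' set of original maxima it grew from, which are mutually separated by the
#' minimum peak distance and therefore stay distinct even where two
#' components transiently touch. Components supported by fewer than
#' `min_segment_rows` rows are discarded as noise.
#'
#' @param points Logical point mask from [rowwise_maxima()].
#' @param config A [cep_config()].
#' @return List of segments, each a data frame with `row` and `x` (column
#'   position), ordered by increasing row; a segment may carry more than one
#'   point in a row where strands touch.
#' @export
close_and_skeletonize <- function(points, config) {
  gap <- to_pixels(config$closing_gap_um, config$calibration)
  # peak positions jitter laterally by a pixel or two between rows; a small
  # isotropic dilation restores 8-connectivity along a strand before the
  # vertical closing bridges missing rows
  pts <- ebi_morph(points * 1.0, EBImage::makeBrush(3, "box"), "dilate")
  closed <- ebi_morph(pts, line_brush(gap, "vertical"),
                      "closing") > 0.5
  labels <- label_mask(closed)
  nlab <- max(labels)
  if (nlab < 1) return(list())
  # the skeleton of each closed component is the set of original maxima it
  # grew from: those points are already one pixel wide, mutually separated
  # by min_sep, and survive even where two components transiently touch
  pidx <- which(points)
  pr <- (pidx - 1L) %% nrow(points) + 1L
  pc <- (pidx - 1L) %/% nrow(points) + 1L
  plab <- labels[pidx]
  segs <- lapply(seq_len(nlab), function(l) {
    sel <- plab == l
    if (!any(sel)) return(NULL)
    o <- order(pr[sel], pc[sel])
    data.frame(row = pr[sel][o], x = as.numeric(pc[sel][o]))
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  # isolated specks that the closing could not connect are noise, not
  # dendrite evidence
  segs[vapply(segs, function(s) length(unique(s$row)),
              integer(1)) >= config$min_segment_rows]
}

#' Bin skeleton segments into dendrite indices
#'
#' Sweeps rows from the distal end (top of the crop) toward the cell body,
#' assigning every skeleton point to the dendrite whose exponentially
#' weighted running-average x position is nearest. A point farther than
#' `new_track_k * min_sep_um` from every running average opens a new index
#' while fewer than four exist. When two points land on the same index at one
#' row, the one farther from the running average is removed. Running
#' averages update only from accepted points. If more than four plausible
#' columns appear, the four with the most supporting rows are kept and a
#' warning is logged.
#'
#' @param segments [close_and_skeletonize()] output.
#' @param config A [cep_config()].
#' @param n_rows Number of rows in the crop.
#' @return An object of class `"track_set"` (raw: observed points only):
#'   list of tracks with `index`, `rows`, `x` sorted by row; indices are
#'   numbered 1..n from left to right.
#' @export
bin_to_dendrites <- function(segments, config, n_rows) {
  if (!length(segments)) stop("no dendrite segments to bin")
  seg_len <- vapply(segments, function(s) length(unique(s$row)), integer(1))
  pts <- do.call(rbind, Map(function(s, len) {
    s$seg_len <- len
    s
  }, segments, seg_len))
  pts <- pts[order(pts$row, pts$x), , drop = FALSE]
  alpha <- 1 / config$track_memory_rows
  open_thresh <- config$new_track_k *
    to_pixels(config$min_sep_um, config$calibration)
  # only segments with substantial row support may open a dendrite index;
  # short noise segments can at most join an existing track
  open_min <- config$track_open_min_rows
  avgs <- numeric(0)
  tracks <- list()
  blocked <- 0L
  for (r in sort(unique(pts$row))) {
    sel <- pts$row == r
    xs <- pts$x[sel]
    lens <- pts$seg_len[sel]
    # one-to-one greedy matching of row points to running averages: each
    # dendrite index takes at most one point per row, and of two points
    # competing for the same index the farther one is released (it may then
    # claim another index or open a new one)
    taken_pt <- rep(FALSE, length(xs))
    taken_tr <- rep(FALSE, length(avgs))
    if (length(avgs)) {
      d <- abs(outer(xs, avgs, "-"))
      d[d > open_thresh] <- Inf
      repeat {
        if (!any(is.finite(d))) break
        ij <- arrayInd(which.min(d), dim(d))   # ties -> lower track index
        i <- ij[1]; j <- ij[2]
        tracks[[j]]$rows <- c(tracks[[j]]$rows, r)
        tracks[[j]]$x <- c(tracks[[j]]$x, xs[i])
        avgs[j] <- (1 - alpha) * avgs[j] + alpha * xs[i]
        taken_pt[i] <- TRUE; taken_tr[j] <- TRUE
        d[i, ] <- Inf; d[, j] <- Inf
      }
    }
    for (i in which(!taken_pt)) {
      if (lens[i] < open_min) next
      if (length(avgs) < 8L) {      # provisional slots beyond the final four
        avgs <- c(avgs, xs[i])
        tracks[[length(avgs)]] <- list(rows = r, x = xs[i])
      } else {
        blocked <- blocked + 1L
      }
    }
  }
  support <- vapply(tracks, function(t) length(t$rows), integer(1))
  keep <- which(support > 0)
  if (!length(keep)) stop("no dendrites detected")
  if (length(keep) > 4L || blocked > 0L) {
    warning("more than four plausible dendrite columns; ",
            "keeping the four with the longest support")
    keep <- keep[order(support[keep], decreasing = TRUE)[1:4]]
  }
  # left-to-right index order
  keep <- keep[order(vapply(keep, function(j) mean(tracks[[j]]$x),
                            numeric(1)))]
  out <- lapply(seq_along(keep), function(i) {
    t <- tracks[[keep[i]]]
    o <- order(t$rows)
    list(index = i, rows = t$rows[o], x = t$x[o])
  })
  structure(list(tracks = out, n_rows = n_rows), class = "track_set")
}

#' Interpolate and smooth raw tracks
#'
#' Within each track's observed row span, missing rows are filled by
#' piecewise-linear interpolation of x over rows; the path is then smoothed
#' with a moving average of `smooth_window_um`. Observed rows stay flagged so
#' interpolated stretches remain identifiable. Track length is the polyline
#' arc length times the pixel size.
#'
#' @param ts A raw `"track_set"` from [bin_to_dendrites()].
#' @param config A [cep_config()].
#' @param crop Optional `"dendrite_crop"`; when given, per-track mean
#'   intensity is sampled from the original crop under the track.
#' @return A `"track_set"` whose tracks carry `row_start`, `x_of_row`
#'   (one x per row of the span), `observed` (logical), `length_um`,
#'   `mean_intensity`, and empty `break_intervals`.
#' @export
interpolate_and_smooth <- function(ts, config, crop = NULL) {
  stopifnot(inherits(ts, "track_set"))
  w <- to_pixels_odd(config$smooth_window_um, config$calibration)
  p <- config$calibration$pixel_size
  raw_img <- if (!is.null(crop)) crop$image$intensities
  ts$tracks <- lapply(ts$tracks, function(t) {
    span <- t$rows[1]:t$rows[length(t$rows)]
    x <- stats::approx(t$rows, t$x, xout = span, method = "linear",
                       ties = mean)$y
    # a short running median rejects single-row outliers (noise points that
    # slipped into the track) before the linear smoother
    if (length(x) >= 5L) x <- stats::runmed(x, 5, endrule = "keep")
    if (length(x) > w && w > 1L) {
      xp <- c(rep(x[1], w %/% 2), x, rep(x[length(x)], w %/% 2))
      x <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))
      x <- x[!is.na(x)]
    }
    len <- if (length(x) > 1L) sum(sqrt(1 + diff(x)^2)) * p else 0
    mi <- NA_real_
    if (!is.null(raw_img)) {
      cols <- pmin(ncol(raw_img), pmax(1L, round(x)))
      mi <- mean(raw_img[cbind(span, cols)])
    }
    list(index = t$index, rows = t$rows, row_start = span[1], x_of_row = x,
         observed = span %in% t$rows, length_um = len, mean_intensity = mi,
         break_intervals = list())
  })
  ts
}

#' @export
print.track_set <- function(x, ...) {
  cat("Track set:", length(x$tracks), "dendrite track(s)\n")
  for (t in x$tracks) {
    cat(sprintf("  #%d: rows %d-%d (%d observed)%s\n", t$index,
                if (!is.null(t$row_start)) t$row_start else min(t$rows),
                if (!is.null(t$x_of_row))
                  t$row_start + length(t$x_of_row) - 1L else max(t$rows),
                length(t$rows),
                if (!is.null(t$length_um) && length(t$length_um))
                  sprintf(", %.1f um", t$length_um) else ""))
  }
  invisible(x)
}

#' Trace the dendrites of a crop
#'
#' Convenience wrapper chaining [rowwise_maxima()],
#' [close_and_skeletonize()], [bin_to_dendrites()] and
#' [interpolate_and_smooth()] on the local-contrast image of an enhanced
#' crop.
#'
#' @param enh An [enhance_crop()] result.
#' @param config A [cep_config()].
#' @return A smoothed `"track_set"`.
#' @export
track_dendrites <- function(enh, config) {
  lc <- enh$local_contrast
  pts <- rowwise_maxima(lc, config, noise = enh$noise_estimate)
  segs <- close_and_skeletonize(pts, config)
  if (!length(segs)) stop("no dendrites detected")
  raw <- bin_to_dendrites(segs, config, n_rows = nrow(lc))
  interpolate_and_smooth(raw, config, crop = enh$crop)
}
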