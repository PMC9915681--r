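# Degeneration metrics: break detection against the binarised dendrite
# image, bleb-to-dendrite matching, the 19-metric report and the 0-4
# categorical score.

#' Canonical metric schema
#'
#' The fixed, versioned names and order of the 19 degeneration metrics
#' reported per dendrite.
#'
#' @return Character vector of 19 metric names.
#' @export
metric_schema <- function() {
  c("dendrite_length_um", "dendrite_remaining", "break_count",
    "total_break_length_um", "dendrite_mean_intensity", "feature_count",
    "feature_count_per_length", "weighted_feature_count",
    "mean_feature_area_um2", "mean_feature_circularity",
    "mean_feature_extent", "mean_feature_eccentricity",
    "mean_feature_min_caliper_um", "mean_feature_max_caliper_um",
    "mean_feature_intensity", "mean_feature_norm_location",
    "feature_location_dispersion", "mean_feature_distance_from_cell_body_um",
    "degeneration_category")
}

#' Detect breaks along a dendrite track
#'
#' Sequentially walks the rows of a track and tests a small horizontal probe
#' window (plus/minus one expected dendrite width around the track x) against
#' the binarised dendrite image; rows whose probe contains no foreground are
#' break rows, and maximal runs of break rows become break intervals.
#' `dendrite_remaining` is one minus the break-row fraction of the track
#' span.
#'
#' Break runs touching either end of the span are trimmed off rather than
#' counted: where foreground support stops at an extremity, the dendrite
#' simply ends there (tracks can overshoot the blurred tip by a few rows),
#' whereas interior runs are true breaks.
#'
#' @param track One track from an [interpolate_and_smooth()] track set.
#' @param dendrite_mask Binarised (Otsu) dendrite crop, original scale.
#' @param config A [cep_config()].
#' @param crop Optional `"dendrite_crop"`; when given, the track's length
#'   and mean intensity are recomputed on the trimmed span.
#' @return The track (possibly trimmed), with `break_intervals` (list of
#'   half-open `c(row_start, row_end)` in crop coordinates), `break_count`,
#'   `total_break_length_um`, and `dendrite_remaining` filled in.
#' @export
detect_breaks <- function(track, dendrite_mask, config, crop = NULL) {
  hw <- to_pixels(config$dendrite_width_um, config$calibration)
  nc <- ncol(dendrite_mask)
  probe <- function(rows, xs) {
    vapply(seq_along(rows), function(i) {
      x <- round(xs[i])
      cols <- max(1L, x - hw):min(nc, x + hw)
      !any(dendrite_mask[rows[i], cols])
    }, logical(1))
  }
  rows <- track$row_start + seq_along(track$x_of_row) - 1L
  is_break <- probe(rows, track$x_of_row)
  if (all(is_break)) {
    # keep the span; the whole track is one break (fully erased dendrite)
    track$break_intervals <- list(c(rows[1], rows[length(rows)] + 1L))
    track$break_count <- 1L
    track$total_break_length_um <- length(rows) *
      config$calibration$pixel_size
    track$dendrite_remaining <- 0
    return(track)
  }
  first <- which(!is_break)[1]
  last <- max(which(!is_break))
  if (first > 1L || last < length(rows)) {
    keep <- first:last
    track$x_of_row <- track$x_of_row[keep]
    track$observed <- track$observed[keep]
    track$row_start <- rows[first]
    track$rows <- track$rows[track$rows >= rows[first] &
                               track$rows <= rows[last]]
    rows <- rows[keep]
    is_break <- is_break[keep]
    p <- config$calibration$pixel_size
    track$length_um <- if (length(keep) > 1L)
      sum(sqrt(1 + diff(track$x_of_row)^2)) * p else 0
    if (!is.null(crop)) {
      raw <- crop$image$intensities
      cols <- pmin(ncol(raw), pmax(1L, round(track$x_of_row)))
      track$mean_intensity <- mean(raw[cbind(rows, cols)])
    }
  }
  r <- rle(is_break)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- lapply(which(r$values), function(k)
    c(rows[starts[k]], rows[ends[k]] + 1L))
  track$break_intervals <- iv
  track$break_count <- length(iv)
  track$total_break_length_um <- sum(is_break) *
    config$calibration$pixel_size
  track$dendrite_remaining <- 1 - sum(is_break) / length(is_break)
  track
}

# cumulative arc length (um) of a track measured from the cell-body end
# (bottom row of the span); element i corresponds to span row i
track_arc_from_soma <- function(track, config) {
  p <- config$calibration$pixel_size
  steps <- sqrt(1 + diff(track$x_of_row)^2) * p
  # arc measured from the last (bottom, cell-body side) row upward
  rev(c(0, cumsum(rev(steps))))
}

#' Match bleb features to dendrite tracks
#'
#' Assigns every feature to the track minimising the lateral distance
#' between the feature centroid and the track x at the centroid's row,
#' accepting matches within `match_radius_um` (ties to the lower index).
#' Matched features get `norm_location` (arc distance from the cell-body end
#' divided by track length) and `distance_from_cell_body_um`; unmatched
#' features keep `NA` and are excluded from per-dendrite means.
#'
#' @param features A `"bleb_features"` frame (crop coordinates).
#' @param ts A smoothed `"track_set"`.
#' @param config A [cep_config()].
#' @return The features frame with assignment columns filled.
#' @export
match_features <- function(features, ts, config) {
  if (!nrow(features)) return(features)
  p <- config$calibration$pixel_size
  arcs <- lapply(ts$tracks, track_arc_from_soma, config = config)
  for (i in seq_len(nrow(features))) {
    fr <- features$centroid_row[i]; fc <- features$centroid_col[i]
    best <- NULL
    for (j in seq_along(ts$tracks)) {
      t <- ts$tracks[[j]]
      ridx <- round(fr) - t$row_start + 1L
      if (ridx < 1L || ridx > length(t$x_of_row)) next
      d_um <- abs(fc - t$x_of_row[ridx]) * p
      if (d_um <= config$match_radius_um &&
          (is.null(best) || d_um < best$d)) {
        best <- list(j = j, d = d_um, ridx = ridx)
      }
    }
    if (!is.null(best)) {
      t <- ts$tracks[[best$j]]
      features$dendrite_index[i] <- t$index
      dist_um <- arcs[[best$j]][best$ridx]
      features$distance_from_cell_body_um[i] <- dist_um
      features$norm_location[i] <-
        if (t$length_um > 0) min(1, dist_um / t$length_um) else 0
    }
  }
  features
}

#' Assign the 0-4 categorical degeneration score
#'
#' Reproduces the categorical binning used to compare automated results with
#' manual dendrite scoring: more than 85% dendrite remaining with no blebs is
#' 0, fewer than 5 blebs is 1, 5 or more blebs is 2, between 50% and 85%
#' remaining is 3, and 50% or less remaining is 4. Breakage outranks
#' blebbing, so the rules are evaluated in precedence order 4, 3, 0, 2, 1;
#' exactly one category fires for any input. Boundaries come from the
#' configuration (`cat_remaining_hi` = 0.85, `cat_remaining_lo` = 0.50,
#' `cat_bleb_cut` = 5).
#'
#' @param dendrite_remaining Numeric vector in `[0, 1]`.
#' @param feature_count Integer vector of detected blebs.
#' @param config A [cep_config()]; defaults to the standard boundaries.
#' @return Integer vector of categories in `{0, 1, 2, 3, 4}`, with a
#'   `"basis"` attribute naming the rule that fired for each element.
#' @export
categorize <- function(dendrite_remaining, feature_count,
                       config = cep_config(pixel_size = 1)) {
  stopifnot(length(dendrite_remaining) == length(feature_count))
  stopifnot(all(dendrite_remaining >= 0 & dendrite_remaining <= 1))
  hi <- config$cat_remaining_hi; lo <- config$cat_remaining_lo
  cut <- config$cat_bleb_cut
  n <- length(dendrite_remaining)
  cat <- integer(n)
  basis <- character(n)
  for (i in seq_len(n)) {
    r <- dendrite_remaining[i]; b <- feature_count[i]
    if (r <= lo) {
      cat[i] <- 4L; basis[i] <- sprintf("remaining <= %g", lo)
    } else if (r <= hi) {
      cat[i] <- 3L; basis[i] <- sprintf("remaining in (%g, %g]", lo, hi)
    } else if (b == 0) {
      cat[i] <- 0L; basis[i] <- sprintf("remaining > %g, no blebs", hi)
    } else if (b >= cut) {
      cat[i] <- 2L; basis[i] <- sprintf(">= %d blebs", cut)
    } else {
      cat[i] <- 1L; basis[i] <- sprintf("1-%d blebs", cut - 1L)
    }
  }
  structure(cat, basis = basis)
}

#' Compile the 19-metric degeneration report
#'
#' One row per dendrite plus a per-image aggregate row
#' (`dendrite_index = "all"`, metric means over dendrites). Feature-derived
#' means are `NA` ("absent") when a dendrite has no matched features.
#' `weighted_feature_count` is the feature count divided by the fraction of
#' dendrite remaining, i.e. blebs per unit of surviving dendrite.
#'
#' @param ts A `"track_set"` whose tracks have been through
#'   [detect_breaks()].
#' @param features A matched `"bleb_features"` frame.
#' @param config A [cep_config()].
#' @param image_id Identifier written into the report rows.
#' @return A data frame of class `"metric_report"` with columns `image_id`,
#'   `dendrite_index`, then the 19 [metric_schema()] columns in order.
#' @export
compute_report <- function(ts, features, config, image_id = "image") {
  rows <- lapply(ts$tracks, function(t) {
    f <- features[!is.na(features$dendrite_index) &
                    features$dendrite_index == t$index, , drop = FALSE]
    nf <- nrow(f)
    rem <- t$dendrite_remaining
    m <- function(v) if (nf) mean(v) else NA_real_
    data.frame(
      image_id = image_id,
      dendrite_index = as.character(t$index),
      dendrite_length_um = t$length_um,
      dendrite_remaining = rem,
      break_count = t$break_count,
      total_break_length_um = t$total_break_length_um,
      dendrite_mean_intensity = t$mean_intensity,
      feature_count = nf,
      feature_count_per_length = if (t$length_um > 0) nf / t$length_um
                                 else NA_real_,
      weighted_feature_count = if (rem > 0) nf / rem else NA_real_,
      mean_feature_area_um2 = m(f$area_um2),
      mean_feature_circularity = m(f$circularity),
      mean_feature_extent = m(f$extent),
      mean_feature_eccentricity = m(f$eccentricity),
      mean_feature_min_caliper_um = m(f$min_caliper_um),
      mean_feature_max_caliper_um = m(f$max_caliper_um),
      mean_feature_intensity = m(f$mean_intensity),
      mean_feature_norm_location = m(f$norm_location),
      feature_location_dispersion = if (nf > 1) stats::sd(f$norm_location)
                                    else if (nf == 1) 0 else NA_real_,
      mean_feature_distance_from_cell_body_um =
        m(f$distance_from_cell_body_um),
      degeneration_category = as.integer(categorize(rem, nf, config)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = image_id, dendrite_index = "all")
    out[metric_schema()] <- NA_real_
  } else {
    agg <- out[1, , drop = FALSE]
    agg$dendrite_index <- "all"
    for (nm in metric_schema()) {
      v <- out[[nm]]
      agg[[nm]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    out <- rbind(out, agg)
  }
  class(out) <- c("metric_report", "data.frame")
  out
}
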