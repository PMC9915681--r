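# End-to-end pipeline and batch driver: region detection, enhancement,
# feature detection and dendrite tracking, break detection, feature
# matching, 19-metric report and categorical score, with per-image QC.

#' Run the full degeneration pipeline on one image
#'
#' Stages run in order: dendrite-region detection, enhancement, bleb
#' detection in parallel with dendrite tracking, break detection, feature
#' matching, report compilation and categorical scoring. An error check
#' flags images where fewer than two tracks were found or where two tracks
#' coincide for more than `overlap_frac_max` of their rows (overlapping
#' dendrites are scored as breaks, which skews results). Stage failures are
#' captured as QC flags, never raised, so batches keep going.
#'
#' @param img A [projection_image()].
#' @param config A [cep_config()].
#' @param image_id Identifier used in the report.
#' @return An object of class `"cep_analysis"`: `report` (a
#'   `"metric_report"` or `NULL`), `crop`, `features`, `tracks`, `qc`
#'   (list with `ok` and `flags`), `image_id`.
#' @export
run_pipeline <- function(img, config, image_id = "image") {
  flags <- character(0)
  out <- list(image_id = image_id, report = NULL, crop = NULL,
              features = NULL, tracks = NULL)
  res <- tryCatch({
    d <- dim(img$intensities)
    if (any(d < 64L)) stop("image smaller than 64 x 64 pixels")
    crop <- detect_dendrite_region(img, config)
    enh <- enhance_crop(crop, config)
    blebs <- detect_blebs(crop, config)
    flags <- c(flags, blebs$qc_warning)
    tracks <- withCallingHandlers(
      track_dendrites(enh, config),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    dmask <- otsu_mask(crop$image$intensities, config)
    tracks$tracks <- lapply(tracks$tracks, detect_breaks,
                            dendrite_mask = dmask, config = config,
                            crop = crop)
    features <- match_features(blebs$features, tracks, config)
    report <- compute_report(tracks, features, config, image_id = image_id)
    if (length(tracks$tracks) < 2L) {
      flags <- c(flags, "fewer than 2 dendrite tracks found")
    }
    ov <- track_overlap_fraction(tracks, config)
    if (is.finite(ov) && ov > config$overlap_frac_max) {
      flags <- c(flags, sprintf(
        "tracks overlap for %.0f%% of rows; overlaps are scored as breaks",
        100 * ov))
    }
    list(crop = crop, features = features, tracks = tracks, report = report)
  }, error = function(e) {
    flags <<- c(flags, paste("pipeline failure:", conditionMessage(e)))
    NULL
  })
  if (!is.null(res)) out[names(res)] <- res
  out$qc <- list(ok = is.null(out$report) == FALSE &&
                   !any(startsWith(flags, "pipeline failure")),
                 flags = flags)
  structure(out, class = "cep_analysis")
}

# fraction of rows (over the union of spans) where two tracks come closer
# than half the minimum separation
track_overlap_fraction <- function(ts, config) {
  if (length(ts$tracks) < 2L) return(0)
  tol <- to_pixels(config$min_sep_um, config$calibration) / 2
  spans <- lapply(ts$tracks, function(t)
    seq(t$row_start, length.out = length(t$x_of_row)))
  all_rows <- sort(unique(unlist(spans)))
  n_overlap <- 0L
  for (r in all_rows) {
    xs <- unlist(lapply(seq_along(ts$tracks), function(j) {
      i <- r - ts$tracks[[j]]$row_start + 1L
      if (i >= 1L && i <= length(ts$tracks[[j]]$x_of_row))
        ts$tracks[[j]]$x_of_row[i]
    }))
    if (length(xs) > 1L && min(diff(sort(xs))) < tol) {
      n_overlap <- n_overlap + 1L
    }
  }
  n_overlap / length(all_rows)
}

#' @export
print.cep_analysis <- function(x, ...) {
  cat("CEP degeneration analysis:", x$image_id, "\n")
  if (!x$qc$ok) {
    cat("  QC FAILED:", paste(x$qc$flags, collapse = "; "), "\n")
    return(invisible(x))
  }
  if (length(x$qc$flags)) {
    cat("  QC flags:", paste(x$qc$flags, collapse = "; "), "\n")
  }
  r <- x$report[x$report$dendrite_index != "all", ]
  cat(sprintf(
    "  %d dendrite(s): remaining %s, blebs %s, categories %s\n",
    nrow(r),
    paste(sprintf("%.2f", r$dendrite_remaining), collapse = "/"),
    paste(r$feature_count, collapse = "/"),
    paste(r$degeneration_category, collapse = "/")))
  invisible(x)
}

#' @export
summary.cep_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$report)) {
    agg <- object$report[object$report$dendrite_index == "all", ]
    cat("Per-image aggregate metrics:\n")
    for (nm in metric_schema()) {
      cat(sprintf("  %-42s %s\n", nm,
                  ifelse(is.na(agg[[nm]]), "absent",
                         sprintf("%.4g", agg[[nm]]))))
    }
  }
  invisible(object)
}

#' Plot a pipeline result
#'
#' Shows the dendrite crop with the traced dendrites as coloured polylines
#' (per-dendrite glyphs at the distal end), detected features as rectangles,
#' and break intervals as dashed segments. Mirrors the QC overlays of the
#' interactive tool.
#'
#' @param x A `"cep_analysis"`.
#' @param ... Unused.
#' @export
plot.cep_analysis <- function(x, ...) {
  if (is.null(x$crop)) {
    graphics::plot.new(); graphics::title("QC failure: no crop")
    return(invisible(x))
  }
  m <- x$crop$image$intensities
  scale <- 2^x$crop$image$bit_depth - 1
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), ]) / scale,
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  xlab = "col (px)", ylab = "row (px, top up)",
                  main = x$image_id)
  flip <- function(r) nrow(m) - r + 1
  cols <- c("red", "gold", "cyan", "magenta")
  glyphs <- c(8, 15, 17, 16)   # star, square, triangle, circle
  for (t in x$tracks$tracks) {
    rows <- seq(t$row_start, length.out = length(t$x_of_row))
    graphics::lines(t$x_of_row, flip(rows), col = cols[t$index], lwd = 2)
    graphics::points(t$x_of_row[1], flip(rows[1]), pch = glyphs[t$index],
                     col = cols[t$index], cex = 1.4)
    for (iv in t$break_intervals) {
      seg <- rows >= iv[1] & rows < iv[2]
      graphics::lines(t$x_of_row[seg], flip(rows[seg]), col = "white",
                      lty = 2, lwd = 2)
    }
  }
  f <- x$features
  if (!is.null(f) && nrow(f)) {
    hw <- sqrt(f$area_um2) / x$crop$image$calibration$pixel_size / 2
    graphics::rect(f$centroid_col - hw, flip(f$centroid_row + hw),
                   f$centroid_col + hw, flip(f$centroid_row - hw),
                   border = "orange", lwd = 1.5)
  }
  invisible(x)
}

#' Process a folder (or files) of images
#'
#' Images are processed in sorted file-name order; per-image failures become
#' QC records and never abort the batch. Writes the aggregate CSV report,
#' the JSON parameter side-car, a QC summary CSV, and (optionally) per-image
#' overlay PNGs to the output directory.
#'
#' @param input Directory containing `.tif`/`.tiff`/`.png` images, or a
#'   character vector of image paths.
#' @param config A [cep_config()].
#' @param output_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param save_overlays Write per-image overlay PNGs.
#' @return List of class `"cep_batch"`: `analyses` (per image), `report`
#'   (combined `"metric_report"`), `qc` (data frame), `paths`.
#' @export
run_batch <- function(input, config, output_dir = NULL,
                      save_overlays = FALSE) {
  files <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
               full.names = TRUE)
  } else input
  files <- sort(files)
  if (!length(files)) stop("no readable images in input")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  analyses <- vector("list", length(files))
  for (i in seq_along(files)) {
    id <- tools::file_path_sans_ext(basename(files[i]))
    t0 <- proc.time()[["elapsed"]]
    ana <- tryCatch({
      img <- load_image(files[i], config$calibration)
      run_pipeline(img, config, image_id = id)
    }, error = function(e) {
      structure(list(image_id = id, report = NULL, crop = NULL,
                     features = NULL, tracks = NULL,
                     qc = list(ok = FALSE,
                               flags = paste("load failure:",
                                             conditionMessage(e)))),
                class = "cep_analysis")
    })
    ana$elapsed_s <- proc.time()[["elapsed"]] - t0
    analyses[[i]] <- ana
    if (save_overlays && !is.null(output_dir) && !is.null(ana$crop)) {
      grDevices::png(file.path(output_dir, paste0(id, "_overlay.png")),
                     width = 900, height = 700)
      plot(ana)
      grDevices::dev.off()
    }
  }
  reports <- Filter(Negate(is.null), lapply(analyses, `[[`, "report"))
  combined <- if (length(reports)) {
    r <- do.call(rbind, reports)
    class(r) <- c("metric_report", "data.frame")
    r
  } else NULL
  qc <- do.call(rbind, lapply(analyses, function(a) data.frame(
    image_id = a$image_id, ok = a$qc$ok,
    flags = paste(a$qc$flags, collapse = "; "),
    elapsed_s = round(a$elapsed_s, 3))))
  paths <- character(0)
  if (!is.null(output_dir)) {
    rep_path <- file.path(output_dir, "metric_report.csv")
    write_report(reports, rep_path, config = config)
    qc_path <- file.path(output_dir, "qc_summary.csv")
    utils::write.csv(qc, qc_path, row.names = FALSE)
    paths <- c(report = rep_path, qc = qc_path,
               params = paste0(rep_path, ".params.json"))
  }
  structure(list(analyses = analyses, report = combined, qc = qc,
                 paths = paths),
            class = "cep_batch")
}

#' @export
print.cep_batch <- function(x, ...) {
  cat("CEP batch:", nrow(x$qc), "image(s),", sum(x$qc$ok), "scored,",
      sum(!x$qc$ok), "QC failure(s)\n")
  invisible(x)
}
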