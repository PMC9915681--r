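# Metric-report file I/O: CSV (one row per dendrite plus per-image
# aggregates) with a JSON side-car of run parameters.

#' Write a batch of metric reports to CSV
#'
#' Column order is fixed: `image_id`, `dendrite_index`, then the 19
#' [metric_schema()] metrics. Values round-trip at full double precision
#' (written with 17 significant digits). When a configuration is supplied, a
#' JSON side-car `<path>.params.json` records the full set of run parameters
#' (pixel size, thresholds, software version).
#'
#' @param reports A `"metric_report"` or list of them (possibly empty).
#' @param path Output CSV path.
#' @param config Optional [cep_config()] for the side-car.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, config = NULL) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  cols <- c("image_id", "dendrite_index", metric_schema())
  if (length(reports)) {
    stopifnot(all(vapply(reports, function(r)
      all(cols %in% names(r)), logical(1))))
    df <- do.call(rbind, lapply(reports, function(r) r[, cols, drop = FALSE]))
  } else {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  df[num] <- lapply(df[num], function(v) ifelse(v == "NA", "", v))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to: ", path)
  if (!is.null(config)) {
    config_to_json(config, paste0(path, ".params.json"))
  }
  invisible(path)
}

#' Read a metric-report CSV
#'
#' @param path CSV written by [write_report()].
#' @return A data frame of class `"metric_report"`.
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character",
                                       dendrite_index = "character"))
  expect <- c("image_id", "dendrite_index", metric_schema())
  if (!identical(names(df), expect)) {
    stop("file does not follow the canonical metric schema: ", path)
  }
  class(df) <- c("metric_report", "data.frame")
  df
}
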