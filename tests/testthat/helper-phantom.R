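# Shared fixtures: phantoms are rendered once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

std_config <- function(...) cep_config(pixel_size = 0.325, ...)

# the standard validation suite, rendered once
get_suite <- function() {
  if (is.null(.fixture_env$suite)) {
    .fixture_env$suite <- phantom_suite(seed = 42)
  }
  .fixture_env$suite
}

# full pipeline result for a named suite fixture, cached
get_analysis <- function(name) {
  key <- paste0("ana_", name)
  if (is.null(.fixture_env[[key]])) {
    fx <- get_suite()[[name]]
    .fixture_env[[key]] <- run_pipeline(fx$image, std_config(), image_id = name)
  }
  .fixture_env[[key]]
}

# map a track (crop coordinates) onto phantom truth columns; returns the
# mean absolute deviation in pixels over rows where both are defined
track_mad_vs_truth <- function(ana, truth, index) {
  tr <- ana$tracks$tracks[[index]]
  ro <- ana$crop$transform$row_offset
  co <- ana$crop$transform$col_offset
  rows <- seq(tr$row_start, length.out = length(tr$x_of_row)) + ro
  sel <- rows %in% truth$path_rows
  gt <- truth$x_of_row[match(rows[sel], truth$path_rows), index]
  mean(abs(tr$x_of_row[sel] + co - gt))
}

# hit-rate bleb recall and false-positive count at a physical radius (um)
bleb_recall_fp <- function(ana, truth, radius_um = 1.5) {
  f <- ana$features
  tb <- truth$blebs
  p <- ana$crop$image$calibration$pixel_size
  if (is.null(tb) || !nrow(tb)) {
    return(list(recall = NA_real_, fp = if (is.null(f)) 0L else nrow(f)))
  }
  if (is.null(f) || !nrow(f)) return(list(recall = 0, fp = 0L))
  ro <- ana$crop$transform$row_offset
  co <- ana$crop$transform$col_offset
  d <- sqrt(outer(tb$row, f$centroid_row + ro, "-")^2 +
              outer(tb$col, f$centroid_col + co, "-")^2) * p
  list(recall = mean(apply(d, 1, min) <= radius_um),
       fp = sum(apply(d, 2, min) > radius_um))
}

# minimal dendrite_crop wrapper around a raw intensity matrix, for testing
# measurement code without running region detection
make_crop <- function(m, pixel_size = 0.325, bit_depth = 16L) {
  structure(
    list(image = projection_image(m, pixel_calibration(pixel_size),
                                  bit_depth = bit_depth),
         mask = m > 0,
         transform = list(rotation_angle = 0, row_offset = 0L,
                          col_offset = 0L, flipped = FALSE,
                          original_soma_side = "bottom"),
         cell_body_side = "bottom"),
    class = "dendrite_crop")
}

# draw a filled disk into a matrix
draw_disk <- function(m, r0, c0, radius, value = 1) {
  rw <- max(1, floor(r0 - radius)):min(nrow(m), ceiling(r0 + radius))
  cw <- max(1, floor(c0 - radius)):min(ncol(m), ceiling(c0 + radius))
  d2 <- outer((rw - r0)^2, (cw - c0)^2, "+")
  m[rw, cw][d2 <= radius^2] <- value
  m
}
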