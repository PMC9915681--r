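cfg <- std_config()

test_that("row profiles yield the k most intense well-separated peaks", {
  x <- seq_len(200)
  centres <- c(40, 80, 120, 160)
  prof <- rowSums(vapply(centres, function(c0) exp(-(x - c0)^2 / 8),
                         numeric(200)))
  pk <- cepscore:::profile_peaks(prof, floor = 0.2, min_dist = 5, k = 4)
  expect_identical(length(pk), 4L)
  expect_true(all(abs(sort(pk) - centres) <= 1))

  # flat row: nothing exceeds the prominence floor
  expect_identical(cepscore:::profile_peaks(rep(1, 100), 1.5, 5, 4),
                   integer(0))

  # six peaks of graded height: the four most intense survive (top-k oracle)
  h <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5)
  centres6 <- c(20, 50, 80, 110, 140, 170)
  prof6 <- rowSums(vapply(seq_along(h), function(i)
    h[i] * exp(-(x - centres6[i])^2 / 8), numeric(200)))
  pk6 <- cepscore:::profile_peaks(prof6, 0.1, 5, 4)
  oracle <- sort(centres6[order(h, decreasing = TRUE)[1:4]])
  expect_true(all(abs(sort(pk6) - oracle) <= 1))
})

test_that("vertical closing bridges sub-element gaps only", {
  cfg1 <- cep_config(pixel_size = 0.325, min_segment_rows = 1L)
  # dotted vertical line with 2-px gaps, closing gap 5 px: one segment
  pts <- matrix(FALSE, 60, 30)
  pts[seq(5, 55, by = 3), 15] <- TRUE
  cfg_gap5 <- cep_config(pixel_size = 1, closing_gap_um = 5,
                         min_segment_rows = 1L)
  segs <- close_and_skeletonize(pts, cfg_gap5)
  expect_identical(length(segs), 1L)
  # two dots 20 px apart with the same element: two segments
  pts2 <- matrix(FALSE, 60, 30)
  pts2[c(10, 30), 15] <- TRUE
  segs2 <- close_and_skeletonize(pts2, cfg_gap5)
  expect_identical(length(segs2), 2L)
})

test_that("a break-free phantom point mask produces exactly four segments", {
  fx <- get_suite()$clean
  crop <- detect_dendrite_region(fx$image, cfg)
  enh <- enhance_crop(crop, cfg)
  pts <- rowwise_maxima(enh$local_contrast, cfg)
  segs <- close_and_skeletonize(pts, cfg)
  expect_identical(length(segs), 4L)
})

test_that("binning assigns parallel strands left to right with a four-track cap", {
  # four clean parallel strands
  segs <- lapply(c(10, 25, 40, 55), function(x0)
    data.frame(row = 1:80, x = x0))
  ts <- bin_to_dendrites(segs, cfg, 80)
  expect_identical(length(ts$tracks), 4L)
  expect_equal(vapply(ts$tracks, function(t) mean(t$x), numeric(1)),
               c(10, 25, 40, 55))
  expect_identical(vapply(ts$tracks, `[[`, integer(1), "index"), 1:4)

  # a fifth strand cannot open a fifth index
  segs5 <- lapply(c(10, 22, 34, 46, 58), function(x0)
    data.frame(row = 1:80, x = x0))
  expect_warning(ts5 <- bin_to_dendrites(segs5, cfg, 80),
                 "more than four")
  expect_lte(length(ts5$tracks), 4L)
  # no row carries more than 4 distinct indices by construction
  rows_used <- unlist(lapply(ts5$tracks, `[[`, "rows"))
  expect_lte(max(table(rows_used)), 4L)
})

test_that("crossing strands keep one point per index per row", {
  # two strands crossing at a shallow angle
  segs <- list(data.frame(row = 1:100, x = 20 + 0.15 * (1:100)),
               data.frame(row = 1:100, x = 35 - 0.15 * (1:100)))
  ts <- bin_to_dendrites(segs, cfg, 100)
  expect_lte(length(ts$tracks), 2L)
  for (t in ts$tracks) expect_false(any(duplicated(t$rows)))
})

test_that("interpolation fills holes and reproduces analytic arc lengths", {
  p <- cfg$pixel_size
  # straight track with a 10-row hole: filled x constant, length = span
  tr <- list(index = 1L, rows = c(1:30, 41:100), x = rep(12, 90))
  ts <- structure(list(tracks = list(tr), n_rows = 100), class = "track_set")
  sm <- interpolate_and_smooth(ts, cfg)
  t1 <- sm$tracks[[1]]
  expect_identical(length(t1$x_of_row), 100L)
  expect_true(all(abs(t1$x_of_row - 12) < 1e-9))
  expect_equal(t1$length_um, 99 * p)
  expect_identical(sum(!t1$observed), 10L)

  # sinusoidal track: polyline length within 2% of the closed-form integral
  rows <- 1:400
  amp <- 6; period <- 120
  xs <- 30 + amp * sin(2 * pi * rows / period)
  tr2 <- list(index = 1L, rows = rows, x = xs)
  ts2 <- structure(list(tracks = list(tr2), n_rows = 400),
                   class = "track_set")
  cfg_nosmooth <- cep_config(pixel_size = 0.325, smooth_window_um = 0.1)
  sm2 <- interpolate_and_smooth(ts2, cfg_nosmooth)
  f <- function(r) sqrt(1 + (amp * 2 * pi / period * cos(2 * pi * r / period))^2)
  analytic <- stats::integrate(f, 1, 400)$value * p
  expect_lt(abs(sm2$tracks[[1]]$length_um - analytic) / analytic, 0.02)

  # the smoother leaves a straight line unchanged
  sm3 <- interpolate_and_smooth(ts, cfg)
  expect_equal(sm3$tracks[[1]]$x_of_row, rep(12, 100))
})

test_that("recovered tracks deviate <= 1.5 px from truth on break-free phantoms", {
  for (nm in c("clean", "blebbed_sparse", "low_snr")) {
    ana <- get_analysis(nm)
    truth <- get_suite()[[nm]]$truth
    expect_identical(length(ana$tracks$tracks), 4L)
    for (d in 1:4) {
      expect_lt(track_mad_vs_truth(ana, truth, d), 1.5)
    }
  }
})

test_that("tracking is mirror-equivariant", {
  fx <- get_suite()$clean
  crop <- detect_dendrite_region(fx$image, cfg)
  enh <- enhance_crop(crop, cfg)
  ts <- track_dendrites(enh, cfg)

  m <- crop$image$intensities[, rev(seq_len(ncol(crop$image$intensities)))]
  cropm <- make_crop(m, cfg$pixel_size, crop$image$bit_depth)
  tsm <- track_dendrites(enhance_crop(cropm, cfg), cfg)

  expect_identical(length(ts$tracks), length(tsm$tracks))
  nc <- ncol(m)
  for (d in seq_along(ts$tracks)) {
    t1 <- ts$tracks[[d]]
    t2 <- tsm$tracks[[length(tsm$tracks) + 1L - d]]   # index order reverses
    common <- intersect(seq(t1$row_start, length.out = length(t1$x_of_row)),
                        seq(t2$row_start, length.out = length(t2$x_of_row)))
    x1 <- t1$x_of_row[common - t1$row_start + 1L]
    x2 <- t2$x_of_row[common - t2$row_start + 1L]
    expect_lt(mean(abs(x1 - (nc + 1 - x2))), 1.0)
  }
})

test_that("hairpin kinks are smoothed through, not followed", {
  # documented limitation: a turn >= 90 degrees is interpolated across
  ana <- get_analysis("hairpin")
  expect_true(ana$qc$ok)
  expect_identical(length(ana$tracks$tracks), 4L)
  # every track remains a single-valued, smooth function of row
  for (t in ana$tracks$tracks) {
    expect_lt(max(abs(diff(t$x_of_row))), 3)
  }
  r <- ana$report[ana$report$dendrite_index != "all", ]
  expect_true(all(r$dendrite_remaining > 0.9))
})
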