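cfg <- std_config()

mk_track <- function(rows, x, p = cfg$pixel_size) {
  list(index = 1L, rows = rows, row_start = rows[1],
       x_of_row = x, observed = rep(TRUE, length(x)),
       length_um = sum(sqrt(1 + diff(x)^2)) * p,
       mean_intensity = 100, break_intervals = list())
}

test_that("break detection finds interior gaps and trims overshoot at the ends", {
  mask <- matrix(FALSE, 100, 21)
  mask[, 10:12] <- TRUE            # continuous dendrite at x ~ 11
  tr <- mk_track(1:100, rep(11, 100))
  out <- detect_breaks(tr, mask, cfg)
  expect_identical(out$break_count, 0L)
  expect_equal(out$dendrite_remaining, 1.0)

  # one 20-row interior gap in 100 rows: remaining 0.8
  mask2 <- mask; mask2[41:60, ] <- FALSE
  out2 <- detect_breaks(tr, mask2, cfg)
  expect_identical(out2$break_count, 1L)
  expect_equal(out2$dendrite_remaining, 0.8)
  expect_equal(out2$break_intervals[[1]], c(41, 61))
  expect_equal(out2$total_break_length_um, 20 * cfg$pixel_size)

  # fully erased dendrite: remaining 0
  out3 <- detect_breaks(tr, mask & FALSE, cfg)
  expect_equal(out3$dendrite_remaining, 0)

  # leading/trailing unsupported rows shrink the span instead of counting
  mask4 <- mask; mask4[1:10, ] <- FALSE; mask4[91:100, ] <- FALSE
  out4 <- detect_breaks(tr, mask4, cfg)
  expect_equal(out4$dendrite_remaining, 1.0)
  expect_identical(out4$row_start, 11L)
  expect_identical(length(out4$x_of_row), 80L)
})

test_that("remaining plus break fraction accounts for every row", {
  for (nm in c("broken_20", "broken_50", "broken_80")) {
    ana <- get_analysis(nm)
    for (t in ana$tracks$tracks) {
      span <- length(t$x_of_row)
      break_rows <- t$total_break_length_um / cfg$pixel_size
      expect_equal(t$dendrite_remaining + break_rows / span, 1.0,
                   tolerance = 1e-9)
    }
  }
})

test_that("features are matched to the nearest track with documented ties", {
  ts <- structure(list(tracks = list(
    mk_track(1:100, rep(10, 100)),
    within(mk_track(1:100, rep(20, 100)), index <- 2L)
  ), n_rows = 100), class = "track_set")
  f <- data.frame(feature = 1:3,
                  centroid_row = c(50, 50, 50),
                  centroid_col = c(19, 15, 90),
                  area_um2 = 1, circularity = 1, extent = 1,
                  eccentricity = 0, min_caliper_um = 1, max_caliper_um = 1,
                  mean_intensity = 1, dendrite_index = NA_integer_,
                  norm_location = NA_real_,
                  distance_from_cell_body_um = NA_real_)
  out <- match_features(f, ts, cfg)
  expect_identical(out$dendrite_index[1], 2L)     # nearest
  expect_identical(out$dendrite_index[2], 1L)     # equidistant -> lower index
  expect_true(is.na(out$dendrite_index[3]))       # beyond matching radius
  # feature at row 50 of a 100-row vertical track: mid-arc
  expect_equal(out$norm_location[1], 0.5, tolerance = 0.02)
})

test_that("phantom bleb arc positions are recovered within 0.05", {
  # 0.05 at the default SNR; at SNR 5 the track-span endpoints wobble by a
  # few rows, which propagates into the arc normalisation
  tol <- c(blebbed_sparse = 0.05, low_snr = 0.10)
  for (nm in names(tol)) {
    ana <- get_analysis(nm)
    truth <- get_suite()[[nm]]$truth
    f <- ana$features[!is.na(ana$features$dendrite_index), ]
    ro <- ana$crop$transform$row_offset
    for (i in seq_len(nrow(f))) {
      truth_i <- which.min(abs(truth$blebs$row - (f$centroid_row[i] + ro)))
      expect_identical(f$dendrite_index[i],
                       as.integer(truth$blebs$dendrite[truth_i]))
      expect_lt(abs(f$norm_location[i] - truth$blebs$arc_frac[truth_i]),
                tol[[nm]])
    }
  }
})

test_that("report formulas match a straight-line recomputation", {
  # 100 um dendrite with 5 features -> 0.05 features per um;
  # remaining 0.5 with 4 features -> weighted count 8
  p <- cfg$pixel_size
  n_rows <- round(100 / p) + 1
  t1 <- mk_track(1:n_rows, rep(10, n_rows))
  t1$dendrite_remaining <- 1; t1$break_count <- 0L
  t1$total_break_length_um <- 0
  f <- do.call(rbind, replicate(5, {
    data.frame(feature = 1, centroid_row = 50, centroid_col = 10,
               area_um2 = 2, circularity = 0.8, extent = 0.7,
               eccentricity = 0.5, min_caliper_um = 1, max_caliper_um = 2,
               mean_intensity = 50, dendrite_index = 1L,
               norm_location = 0.5, distance_from_cell_body_um = 50)
  }, simplify = FALSE))
  ts <- structure(list(tracks = list(t1), n_rows = n_rows),
                  class = "track_set")
  rep1 <- compute_report(ts, f, cfg, "a")
  r <- rep1[rep1$dendrite_index == "1", ]
  expect_equal(r$feature_count_per_length, 5 / r$dendrite_length_um)
  expect_equal(round(r$feature_count_per_length, 2), 0.05)

  t2 <- t1; t2$dendrite_remaining <- 0.5
  ts2 <- structure(list(tracks = list(t2), n_rows = n_rows),
                   class = "track_set")
  rep2 <- compute_report(ts2, f[1:4, ], cfg, "b")
  expect_equal(rep2$weighted_feature_count[1], 8.0)

  # formula-by-formula oracle on a phantom analysis
  ana <- get_analysis("blebbed_sparse")
  rep <- ana$report[ana$report$dendrite_index != "all", ]
  f <- ana$features
  for (i in seq_len(nrow(rep))) {
    t <- ana$tracks$tracks[[i]]
    fi <- f[!is.na(f$dendrite_index) & f$dendrite_index == t$index, ]
    expect_equal(rep$feature_count[i], nrow(fi))
    expect_equal(rep$dendrite_length_um[i], t$length_um)
    expect_equal(rep$break_count[i], t$break_count)
    if (nrow(fi)) {
      expect_equal(rep$mean_feature_area_um2[i], mean(fi$area_um2))
      expect_equal(rep$mean_feature_norm_location[i],
                   mean(fi$norm_location))
      expect_equal(rep$weighted_feature_count[i],
                   nrow(fi) / t$dendrite_remaining)
    } else {
      expect_true(is.na(rep$mean_feature_area_um2[i]))
    }
  }
  # aggregate row is the mean over dendrites
  agg <- ana$report[ana$report$dendrite_index == "all", ]
  expect_equal(agg$dendrite_length_um, mean(rep$dendrite_length_um))
})

test_that("degradation is monotone: breaks reduce remaining, blebs add counts", {
  clean <- get_analysis("clean")$report
  broken <- get_analysis("broken_20")$report
  blebbed <- get_analysis("blebbed_sparse")$report
  agg <- function(r) r[r$dendrite_index == "all", ]
  expect_lt(agg(broken)$dendrite_remaining, agg(clean)$dendrite_remaining)
  expect_gt(agg(blebbed)$feature_count, agg(clean)$feature_count)
})

test_that("categorical scoring follows the published binning with precedence", {
  expect_identical(as.integer(categorize(0.90, 0)), 0L)
  expect_identical(as.integer(categorize(0.95, 3)), 1L)
  expect_identical(as.integer(categorize(0.95, 7)), 2L)
  expect_identical(as.integer(categorize(0.70, 0)), 3L)
  expect_identical(as.integer(categorize(0.40, 0)), 4L)
  # breakage outranks blebbing
  expect_identical(as.integer(categorize(0.40, 7)), 4L)
  expect_identical(as.integer(categorize(0.70, 7)), 3L)

  # exhaustive truth-table oracle on the (remaining x blebs) grid
  oracle <- function(r, b) {
    if (r <= 0.50) 4L
    else if (r <= 0.85) 3L
    else if (b == 0) 0L
    else if (b >= 5) 2L
    else 1L
  }
  grid <- expand.grid(r = seq(0, 1, by = 0.05), b = 0:10)
  got <- as.integer(categorize(grid$r, grid$b))
  want <- mapply(oracle, grid$r, grid$b)
  expect_identical(got, as.integer(want))
})
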