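cfg <- std_config()

test_that("enhancement contracts: 4x shape, flat stays flat, gradient removed", {
  flat <- make_crop(matrix(500, 60, 40))
  enh <- enhance_crop(flat, cfg)
  expect_identical(dim(enh$intensities), c(240L, 160L))
  expect_lt(diff(range(enh$intensities)), 1e-6)

  # a strong lateral illumination gradient is flattened by the background
  # subtraction: the medians of the background columns (dendrite columns
  # excluded) are flat to within 5% of the dynamic range
  fx <- render_phantom(phantom_spec(gradient = c(0, 0.6), snr = Inf,
                                    seed = 2))
  crop <- detect_dendrite_region(fx$image, cfg)
  enh2 <- enhance_crop(crop, cfg)
  prof <- apply(enh2$intensities, 2, stats::median)
  bg_cols <- prof < stats::quantile(prof, 0.5)
  expect_lt(diff(range(prof[bg_cols])),
            0.05 * diff(range(enh2$intensities)))
})

test_that("clean dendrites yield no bleb seeds; a bleb yields one seed at its site", {
  clean <- get_suite()$clean
  crop <- detect_dendrite_region(clean$image, cfg)
  enh <- enhance_crop(crop, cfg)
  cand <- segment_candidates(enh, cfg)
  expect_equal(max(cand$seeds), 0)

  fx <- render_phantom(phantom_spec(
    blebs = data.frame(dendrite = 2, arc_frac = 0.5, diameter_um = 1.5,
                       gain = 2.5),
    seed = 9))
  crop2 <- detect_dendrite_region(fx$image, cfg)
  enh2 <- enhance_crop(crop2, cfg)
  cand2 <- segment_candidates(enh2, cfg)
  expect_gte(max(cand2$seeds), 1)
  pr <- cepscore:::region_props(cand2$seeds)
  # strongest seed lies within 3 crop pixels of the true bleb centre
  pr <- pr[which.max(pr$area), ]
  truth_r <- (fx$truth$blebs$row[1] - crop2$transform$row_offset)
  truth_c <- (fx$truth$blebs$col[1] - crop2$transform$col_offset)
  expect_lt(abs(pr$centroid_row / 4 - truth_r), 3)
  expect_lt(abs(pr$centroid_col / 4 - truth_c), 3)
})

test_that("a too-short erosion line is flagged as a QC warning", {
  crop <- make_crop(matrix(runif(60 * 40, 0, 100), 60, 40))
  enh <- enhance_crop(crop, cep_config(pixel_size = 0.325,
                                       erode_len_um = 0.5))
  cand <- segment_candidates(enh, cep_config(pixel_size = 0.325,
                                             erode_len_um = 0.5))
  expect_match(cand$qc_warning, "erosion length")
})

test_that("Chan-Vese refinement rounds out jagged seeds and falls back on collapse", {
  # bright disk on dark: refined mask should be more circular than a jagged
  # horizontal-biased seed
  img <- matrix(0.05, 80, 80)
  img <- draw_disk(img, 40, 40, 12, value = 0.9)
  seed <- matrix(0, 80, 80)
  seed[38:42, 30:50] <- 1   # jagged horizontal bar seed
  refined <- cepscore:::chan_vese(img, seed > 0, iters = 50)
  expect_false(is.null(refined))
  pr_seed <- cepscore:::region_props(cepscore:::label_mask(seed > 0))
  pr_ref <- cepscore:::region_props(cepscore:::label_mask(refined))
  expect_gt(pr_ref$circularity, pr_seed$circularity)
  expect_gt(pr_ref$area, 0.8 * pi * 144)

  # uniform background: the contour collapses and NULL signals fallback
  expect_null(cepscore:::chan_vese(matrix(0.5, 40, 40),
                                   draw_disk(matrix(0, 40, 40), 20, 20, 5) > 0,
                                   iters = 20))
})

test_that("feature measurements match analytic shapes", {
  crop <- make_crop(matrix(1000, 100, 100))
  enh <- enhance_crop(crop, cfg)

  # filled square: extent exactly 1
  sq <- matrix(0L, 400, 400); sq[100:149, 100:149] <- 1L
  f <- measure_features(sq, enh, cfg)
  expect_equal(f$extent, 1.0)

  # digital disk of radius 20 px: circularity ~1, calipers ~ diameter
  dk <- matrix(0, 400, 400)
  dk <- draw_disk(dk, 200, 200, 20)
  f2 <- measure_features(cepscore:::label_mask(dk > 0), enh, cfg)
  expect_gt(f2$circularity, 0.9); expect_lt(f2$circularity, 1.1)
  d_um <- 40 * cfg$pixel_size / 4
  expect_lt(abs(f2$min_caliper_um - d_um) / d_um, 0.05)
  expect_lt(abs(f2$max_caliper_um - d_um) / d_um, 0.05)
  expect_equal(f2$area_um2, sum(dk > 0) * (cfg$pixel_size / 4)^2)

  # plus sign: extent well below 0.6 (a cross approaches extent 0)
  cross <- matrix(0L, 400, 400)
  cross[180:220, 195:205] <- 1L
  cross[195:205, 180:220] <- 1L
  f3 <- measure_features(cross, enh, cfg)
  expect_lt(f3$extent, 0.6)
  expect_gt(f3$extent, 0.2)   # consistent with covered bbox fraction
})

test_that("feature detection is invariant under horizontal mirroring", {
  fx <- get_suite()$blebbed_sparse
  crop <- detect_dendrite_region(fx$image, cfg)
  res <- detect_blebs(crop, cfg)

  m <- crop$image$intensities[, rev(seq_len(ncol(crop$image$intensities)))]
  cropm <- make_crop(m, pixel_size = cfg$pixel_size,
                     bit_depth = crop$image$bit_depth)
  resm <- detect_blebs(cropm, cfg)

  expect_identical(nrow(res$features), nrow(resm$features))
  # CLAHE tiling is not perfectly mirror-symmetric, so sizes agree to a
  # small tolerance rather than bitwise
  expect_equal(sort(res$features$area_um2), sort(resm$features$area_um2),
               tolerance = 0.05)
  expect_equal(sort(res$features$max_caliper_um),
               sort(resm$features$max_caliper_um), tolerance = 0.05)
})

test_that("detected size scales quadratically in area and linearly in caliper", {
  diams <- c(1.5, 2.0, 2.5, 3.0)
  areas <- calipers <- numeric(length(diams))
  for (i in seq_along(diams)) {
    fx <- render_phantom(phantom_spec(
      blebs = data.frame(dendrite = 2, arc_frac = 0.5,
                         diameter_um = diams[i], gain = 2.0),
      seed = 21))
    crop <- detect_dendrite_region(fx$image, cfg)
    res <- detect_blebs(crop, cfg)
    f <- res$features[which.max(res$features$area_um2), ]
    areas[i] <- f$area_um2
    calipers[i] <- f$max_caliper_um
  }
  # log-log slopes: 2 for area (quadratic), 1 for caliper (linear),
  # each within 10%
  area_slope <- stats::coef(stats::lm(log(areas) ~ log(diams)))[2]
  expect_lt(abs(area_slope - 2) / 2, 0.10)
  cal_slope <- stats::coef(stats::lm(log(calipers) ~ log(diams)))[2]
  expect_lt(abs(cal_slope - 1), 0.10)
  expect_true(all(diff(areas) > 0))
  expect_true(all(diff(calipers) > 0))
})
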