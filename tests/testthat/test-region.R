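cfg <- std_config()

test_that("cell bodies are located within 3 px of phantom ground truth", {
  fx <- get_suite()$clean
  det <- detect_cell_bodies(fx$image, cfg)
  # truth soma centroid = centroid of the rendered soma mask
  idx <- which(fx$truth$soma_mask)
  truth_centroid <- c(mean((idx - 1) %% nrow(fx$truth$soma_mask) + 1),
                      mean((idx - 1) %/% nrow(fx$truth$soma_mask) + 1))
  expect_lt(sqrt(sum((det$centroid - truth_centroid)^2)), 3)
  # bounding box contains the centroid and the mask is non-empty
  expect_true(any(det$mask))
  expect_true(det$centroid[1] >= det$bbox[1] && det$centroid[1] < det$bbox[2])
  expect_true(det$centroid[2] >= det$bbox[3] && det$centroid[2] < det$bbox[4])
})

test_that("degenerate images fail cell-body detection loudly", {
  zero <- projection_image(matrix(0, 64, 64), pixel_calibration(0.3))
  expect_error(detect_cell_bodies(zero, cfg), "no cell body found")
  flat <- projection_image(matrix(100, 64, 64), pixel_calibration(0.3),
                           bit_depth = 16L)
  expect_error(detect_cell_bodies(flat, cfg), "no cell body found")
})

test_that("a single bright disk is recovered with analytic centroid and bbox", {
  m <- draw_disk(matrix(2, 128, 128), 60, 70, 10, value = 220)
  img <- projection_image(m, pixel_calibration(0.3), bit_depth = 8L)
  det <- detect_cell_bodies(img, cfg)
  expect_lt(sqrt(sum((det$centroid - c(60, 70))^2)), 1.5)
  expect_true(det$bbox[1] >= 48 && det$bbox[2] <= 73)
  expect_true(det$bbox[3] >= 58 && det$bbox[4] <= 83)
})

test_that("orientation recovers phantom rotations to within 3 degrees", {
  fx <- get_suite()$clean
  det <- detect_cell_bodies(fx$image, cfg)
  expect_lt(abs(det$principal_angle), 2)

  fx30 <- get_suite()$rotated_30
  det30 <- detect_cell_bodies(fx30$image, cfg)
  ori <- orient_vertical(fx30$image, det30, cfg)
  expect_lt(abs(abs(ori$angle) - 30), 3)
  # after rotation the foreground axis is near vertical
  expect_lt(abs(ori$detection$principal_angle), 3)
})

test_that("the dendrite-containing half is selected, also under mirroring", {
  fx <- get_suite()$clean
  det <- detect_cell_bodies(fx$image, cfg)
  sp <- split_and_select(fx$image, det, cfg)
  expect_identical(sp$chosen, 1L)        # somas sit below the dendrites
  expect_identical(sp$halves[[1]]$soma_side, "bottom")

  # vertical mirror flips which half holds the dendrites
  m <- fx$image$intensities[rev(seq_len(nrow(fx$image$intensities))), ]
  flipped <- projection_image(m, fx$image$calibration,
                              bit_depth = fx$image$bit_depth)
  detf <- detect_cell_bodies(flipped, cfg)
  spf <- split_and_select(flipped, detf, cfg)
  expect_identical(spf$chosen, 2L)
  expect_identical(spf$halves[[2]]$soma_side, "top")
})

test_that("four vertical bars beat one circle in half selection", {
  m <- matrix(1, 200, 120)
  for (x in c(30, 50, 70, 90)) m[20:80, x + 0:1] <- 180   # bars, upper half
  m <- draw_disk(m, 150, 60, 12, value = 180)             # circle, lower half
  m <- draw_disk(m, 95, 60, 8, value = 250)               # "soma" at split row
  img <- projection_image(m, pixel_calibration(0.3), bit_depth = 8L)
  det <- detect_cell_bodies(img, cfg)
  sp <- split_and_select(img, det, cfg)
  expect_identical(sp$chosen, 1L)
})

test_that("crop keeps the dendrites, excludes somas, and drops edge clutter", {
  fx <- get_suite()$clean
  img <- fx$image
  # inject a clutter blob touching the left edge, at the height of the
  # foreground centre of mass so it does not bias the orientation estimate
  m <- img$intensities
  m <- draw_disk(m, 135, 4, 4, value = 0.5 * max(m))
  img2 <- projection_image(m, img$calibration, bit_depth = img$bit_depth)
  crop <- detect_dendrite_region(img2, cfg)

  ro <- crop$transform$row_offset; co <- crop$transform$col_offset
  nr <- nrow(crop$image$intensities); nc <- ncol(crop$image$intensities)
  # ground-truth dendrite pixels: within one sigma of each path
  sig_px <- 0.32 / 0.325
  inside <- 0L; total <- 0L
  for (d in seq_len(ncol(fx$truth$x_of_row))) {
    for (i in seq_along(fx$truth$path_rows)) {
      r <- fx$truth$path_rows[i]
      for (c in round(fx$truth$x_of_row[i, d]) + (-1:1)) {
        total <- total + 1L
        rr <- r - ro; cc <- c - co
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) inside <- inside + 1L
      }
    }
  }
  expect_gte(inside / total, 0.95)
  # no soma pixels in the crop
  soma_idx <- which(fx$truth$soma_mask, arr.ind = TRUE)
  in_crop <- soma_idx[, 1] - ro >= 1 & soma_idx[, 1] - ro <= nr &
    soma_idx[, 2] - co >= 1 & soma_idx[, 2] - co <= nc
  expect_identical(sum(in_crop), 0L)
  # clutter blob (rows 131-139, cols 1-8) is outside the crop
  expect_true(co >= 8 || ro >= 139 || ro + nr <= 131)
})

test_that("region detection works across a 4x range of pixel sizes", {
  for (p in c(0.1, 0.4)) {
    rows <- round(200 / (p / 0.325) / 4) * 4 + 56
    fx <- render_phantom(phantom_spec(
      image_size = c(max(256, round(256 * 0.325 / p)),
                     max(192, round(192 * 0.325 / p))),
      pixel_size = p,
      margin_rows = round(c(20, 36) * 0.325 / p), seed = 3))
    crop <- detect_dendrite_region(fx$image, cep_config(pixel_size = p))
    ro <- crop$transform$row_offset
    nr <- nrow(crop$image$intensities)
    covered <- mean(fx$truth$path_rows - ro >= 1 &
                      fx$truth$path_rows - ro <= nr)
    expect_gte(covered, 0.95)
  }
})
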