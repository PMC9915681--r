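# Synthetic CEP-like fluorescence phantoms with exact ground truth.
#
# A phantom emulates the geometry the pipeline was designed for: four
# near-vertical curvilinear dendrites of Gaussian cross-section rising from
# bright circular cell bodies at the bottom of the frame, with optional
# circular bleb bumps, break (gap) intervals, a smooth multiplicative
# illumination gradient, an isotropic Gaussian PSF and additive Gaussian
# camera noise.

#' Specify a synthetic CEP phantom
#'
#' Defaults describe a realistic 40x-objective acquisition: a 256 x 192 px
#' 16-bit frame at 0.325 um/pixel, four dendrites 4 um apart spanning 180
#' rows (58.5 um) with a gentle sinusoidal wiggle, Gaussian cross-section of
#' sigma 0.32 um (FWHM ~0.75 um), soma disks of radius 2 um at 0.9 of full
#' scale, dendrite amplitude 0.30 of full scale over a 0.02 background, PSF
#' sigma 0.2 um, and additive noise of amplitude/SNR with SNR 10.
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size um/pixel.
#' @param n_dendrites Number of strands (default 4).
#' @param path_amplitude_um,path_period_um Sinusoidal wiggle of each strand.
#' @param dendrite_sigma_um Gaussian cross-section sigma.
#' @param dendrite_intensity Ridge amplitude as a fraction of full scale.
#' @param spacing_um Lateral spacing between strands.
#' @param soma_radius_um,soma_intensity Cell-body disk geometry/brightness.
#' @param background Background level as a fraction of full scale.
#' @param blebs Data frame with columns `dendrite`, `arc_frac` (fraction of
#'   the path from the cell body, in `[0,1]`), `diameter_um`, `gain`
#'   (amplitude as a multiple of the dendrite amplitude); or `NULL`.
#' @param breaks Data frame with columns `dendrite`, `arc_start_frac`,
#'   either `length_um` or `length_frac` (fraction of path rows); or `NULL`.
#' @param snr Dendrite amplitude / noise sd; `Inf` for noise-free.
#' @param gradient `c(g_row, g_col)` linear multiplicative illumination
#'   coefficients (fractional change across the frame).
#' @param psf_sigma_um Isotropic Gaussian blur applied before noise.
#' @param rotation Whole-image rotation in degrees (0 = dendrites vertical,
#'   somas at the bottom).
#' @param bit_depth 8 or 16.
#' @param margin_rows `c(top, bottom)` rows between the frame edge, the
#'   distal dendrite tips, and the soma centres.
#' @param seed Integer RNG seed; the same spec and seed render bitwise
#'   identically.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_size = c(256L, 192L), pixel_size = 0.325,
                         n_dendrites = 4L, path_amplitude_um = 1.0,
                         path_period_um = 40, dendrite_sigma_um = 0.32,
                         dendrite_intensity = 0.30, spacing_um = 4.0,
                         soma_radius_um = 2.0, soma_intensity = 0.90,
                         background = 0.02, blebs = NULL, breaks = NULL,
                         snr = 10, gradient = c(0, 0), psf_sigma_um = 0.2,
                         rotation = 0, bit_depth = 16L,
                         margin_rows = c(20L, 36L), seed = 1L) {
  spec <- as.list(environment())
  stopifnot(length(image_size) == 2L, all(image_size >= 64L),
            pixel_size > 0, n_dendrites >= 1L, snr > 0)
  if (!is.null(blebs)) {
    stopifnot(all(c("dendrite", "arc_frac", "diameter_um", "gain") %in%
                    names(blebs)))
    if (any(blebs$dendrite < 1 | blebs$dendrite > n_dendrites)) {
      stop("bleb references a dendrite that does not exist")
    }
    if (any(blebs$diameter_um <= 2.355 * dendrite_sigma_um)) {
      stop("bleb diameter must exceed the dendrite width")
    }
  }
  if (!is.null(breaks)) {
    stopifnot(all(c("dendrite", "arc_start_frac") %in% names(breaks)),
              any(c("length_um", "length_frac") %in% names(breaks)))
    if (any(breaks$dendrite < 1 | breaks$dendrite > n_dendrites)) {
      stop("break references a dendrite that does not exist")
    }
  }
  structure(spec, class = "phantom_spec")
}

# row span of the dendrite paths for a spec (top row .. soma row - gap)
phantom_path_rows <- function(spec) {
  r0 <- spec$margin_rows[1] + 1L
  r1 <- spec$image_size[1] - spec$margin_rows[2]
  if (r1 <= r0) stop("image too small for the requested margins")
  c(r0, r1)
}

#' Render a phantom and its ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [projection_image()]) and `truth`, a list
#'   holding per-dendrite true tracks (`x_of_row`, continuous column
#'   positions), break row intervals, true remaining fractions (exactly
#'   `1 - break_rows / path_rows` by construction), bleb centroids, areas and
#'   arc fractions, and the soma mask.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  p <- spec$pixel_size
  scale <- 2^spec$bit_depth - 1
  pr <- phantom_path_rows(spec)
  rows <- pr[1]:pr[2]
  n_rows <- length(rows)
  sig_px <- spec$dendrite_sigma_um / p
  spacing_px <- spec$spacing_um / p
  centre <- (nc + 1) / 2
  offsets <- (seq_len(spec$n_dendrites) -
                (spec$n_dendrites + 1) / 2) * spacing_px
  amp_px <- spec$path_amplitude_um / p
  period_rows <- spec$path_period_um / p
  img <- matrix(spec$background, nr, nc)
  cgrid <- seq_len(nc)

  x_of_row <- matrix(NA_real_, n_rows, spec$n_dendrites)
  break_rows <- vector("list", spec$n_dendrites)
  remaining <- numeric(spec$n_dendrites)
  break_intervals <- vector("list", spec$n_dendrites)

  for (d in seq_len(spec$n_dendrites)) {
    phase <- 2 * pi * (d - 1) / max(1, spec$n_dendrites)
    x <- centre + offsets[d] +
      amp_px * sin(2 * pi * (rows - pr[1]) / period_rows + phase)
    x_of_row[, d] <- x
    bset <- integer(0)
    ivals <- list()
    if (!is.null(spec$breaks)) {
      bk <- spec$breaks[spec$breaks$dendrite == d, , drop = FALSE]
      if (nrow(bk)) {
        for (i in seq_len(nrow(bk))) {
          len_rows <- if (!is.null(bk$length_frac) && !is.na(bk$length_frac[i]))
            round(bk$length_frac[i] * n_rows)
          else round(bk$length_um[i] / p)
          # arc fraction measured from the cell body (bottom of the path);
          # the interval extends from its start toward the cell body
          start <- n_rows - round(bk$arc_start_frac[i] * n_rows)
          i1 <- max(1L, start)
          i2 <- min(n_rows, start + len_rows - 1L)
          if (i2 >= i1) {
            bset <- union(bset, i1:i2)
            ivals[[length(ivals) + 1L]] <- c(rows[i1], rows[i2] + 1L)
          }
        }
      }
    }
    remaining[d] <- 1 - length(bset) / n_rows
    break_rows[[d]] <- bset
    break_intervals[[d]] <- ivals
    amp <- rep(spec$dendrite_intensity, n_rows)
    if (length(bset)) amp[bset] <- 0
    # Gaussian ridge: each row adds a 1-D Gaussian profile centred on x(row)
    for (i in seq_len(n_rows)) {
      if (amp[i] > 0) {
        img[rows[i], ] <- img[rows[i], ] +
          amp[i] * exp(-(cgrid - x[i])^2 / (2 * sig_px^2))
      }
    }
  }

  # blebs: isotropic Gaussian bumps on the dendrite path
  true_blebs <- NULL
  if (!is.null(spec$blebs) && nrow(spec$blebs)) {
    bl <- spec$blebs
    rows_b <- numeric(nrow(bl)); cols_b <- numeric(nrow(bl))
    for (i in seq_len(nrow(bl))) {
      d <- bl$dendrite[i]
      ri <- n_rows - round(bl$arc_frac[i] * (n_rows - 1L))
      ri <- min(max(ri, 1L), n_rows)
      r0 <- rows[ri]; c0 <- x_of_row[ri, d]
      rows_b[i] <- r0; cols_b[i] <- c0
      sb <- (bl$diameter_um[i] / 2.355) / p    # FWHM = stated diameter
      a <- bl$gain[i] * spec$dendrite_intensity
      rwin <- max(1L, floor(r0 - 4 * sb)):min(nr, ceiling(r0 + 4 * sb))
      cwin <- max(1L, floor(c0 - 4 * sb)):min(nc, ceiling(c0 + 4 * sb))
      bump <- a * exp(-(outer((rwin - r0)^2, (cwin - c0)^2, "+")) / (2 * sb^2))
      img[rwin, cwin] <- img[rwin, cwin] + bump
    }
    true_blebs <- data.frame(
      dendrite = bl$dendrite, row = rows_b, col = cols_b,
      arc_frac = bl$arc_frac, diameter_um = bl$diameter_um,
      area_um2 = pi * (bl$diameter_um / 2)^2, gain = bl$gain)
  }

  # somas: bright disks at the proximal (bottom) path ends
  soma_row <- pr[2] + round(spec$soma_radius_um / p) + 2L
  soma_mask <- matrix(FALSE, nr, nc)
  rad_px <- spec$soma_radius_um / p
  for (d in seq_len(spec$n_dendrites)) {
    c0 <- x_of_row[n_rows, d]
    rwin <- max(1L, floor(soma_row - rad_px)):min(nr, ceiling(soma_row + rad_px))
    cwin <- max(1L, floor(c0 - rad_px)):min(nc, ceiling(c0 + rad_px))
    d2 <- outer((rwin - soma_row)^2, (cwin - c0)^2, "+")
    disk <- d2 <= rad_px^2
    img[rwin, cwin][disk] <- pmax(img[rwin, cwin][disk], spec$soma_intensity)
    soma_mask[rwin, cwin] <- soma_mask[rwin, cwin] | disk
    # stalk joining soma to the dendrite end
    stalk_rows <- (pr[2] + 1L):soma_row
    img[stalk_rows, ] <- img[stalk_rows, ] + spec$dendrite_intensity *
      exp(-(matrix(cgrid, length(stalk_rows), nc, byrow = TRUE) - c0)^2 /
            (2 * sig_px^2))
  }

  # illumination gradient (multiplicative plane), PSF blur, rotation, noise
  if (any(spec$gradient != 0)) {
    gr <- 1 + spec$gradient[1] * (seq_len(nr) / nr - 0.5)
    gc <- 1 + spec$gradient[2] * (seq_len(nc) / nc - 0.5)
    img <- img * outer(gr, gc)
  }
  if (spec$psf_sigma_um > 0) {
    img <- from_ebi(EBImage::gblur(as_ebi(img), sigma = spec$psf_sigma_um / p))
  }
  if (spec$rotation != 0) {
    # the canvas grows to the enclosing box so nothing is clipped
    img <- from_ebi(EBImage::rotate(as_ebi(img), angle = spec$rotation,
                                    bg.col = spec$background))
  }
  noise_sd <- if (is.finite(spec$snr)) spec$dendrite_intensity / spec$snr else 0
  if (noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(length(img), 0, noise_sd),
                                  nrow(img), ncol(img)))
  }
  img <- pmin(pmax(img, 0), 1) * scale

  truth <- list(
    path_rows = rows,
    x_of_row = x_of_row,
    break_rows = break_rows,
    break_intervals = break_intervals,
    remaining = remaining,
    blebs = true_blebs,
    soma_mask = soma_mask,
    rotation = spec$rotation)
  list(image = projection_image(img, pixel_calibration(p),
                                bit_depth = spec$bit_depth,
                                source_path = "phantom"),
       truth = truth)
}

#' Deterministic phantom validation suite
#'
#' A fixed battery of twelve rendered phantoms covering the behaviours the
#' pipeline must handle: a clean worm, sparse and dense blebbing, 20/50/80%
#' dendrite loss, combined damage, 30- and 90-degree rotations, a five-strand
#' stressor, a hairpin-kink limitation probe, and a low-SNR acquisition.
#'
#' @param seed Integer seed; fixture i renders with `seed + i`.
#' @param pixel_size um/pixel for all fixtures.
#' @return Named list of fixtures, each `list(name, spec, image, truth)`.
#' @export
phantom_suite <- function(seed = 1L, pixel_size = 0.325) {
  mk_blebs <- function(dend, frac, diam = 2.0, gain = 2.0)
    data.frame(dendrite = dend, arc_frac = frac, diameter_um = diam,
               gain = gain)
  mk_breaks <- function(frac) {
    # one centred interval per dendrite covering `frac` of the path rows
    data.frame(dendrite = 1:4,
               arc_start_frac = 0.5 + frac / 2,
               length_frac = frac)
  }
  specs <- list(
    clean = list(),
    blebbed_sparse = list(blebs = mk_blebs(c(1, 3, 4), c(0.3, 0.6, 0.75))),
    blebbed_dense = list(blebs = mk_blebs(
      rep(1:4, each = 3), rep(c(0.25, 0.5, 0.75), 4))),
    broken_20 = list(breaks = mk_breaks(0.20)),
    broken_50 = list(breaks = mk_breaks(0.50)),
    broken_80 = list(breaks = mk_breaks(0.80)),
    combined = list(blebs = mk_blebs(c(2, 4), c(0.35, 0.65)),
                    breaks = mk_breaks(0.20)),
    rotated_30 = list(rotation = 30),
    rotated_90 = list(rotation = 90),
    five_strand = list(n_dendrites = 5L, spacing_um = 3.5),
    hairpin = list(),                       # kink injected below
    low_snr = list(snr = 5,
                   blebs = mk_blebs(c(1, 2, 3, 4), c(0.3, 0.5, 0.6, 0.8)))
  )
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    args <- c(specs[[i]], list(pixel_size = pixel_size, seed = seed + i))
    spec <- do.call(phantom_spec, args)
    fx <- render_phantom(spec)
    if (names(specs)[i] == "hairpin") fx <- add_hairpin(fx, spec)
    out[[i]] <- c(list(name = names(specs)[i], spec = spec), fx)
  }
  out
}

# Inject a hairpin kink (a turn >= 90 degrees) into dendrite 2 of a rendered
# clean phantom: a short parametric detour that doubles back on itself, the
# geometry the tracker is documented to smooth through rather than follow.
add_hairpin <- function(fx, spec) {
  img <- fx$image$intensities
  p <- spec$pixel_size
  scale <- 2^spec$bit_depth - 1
  sig_px <- spec$dendrite_sigma_um / p
  rows <- fx$truth$path_rows
  n_rows <- length(rows)
  i0 <- round(n_rows * 0.45)
  r0 <- rows[i0]; c0 <- fx$truth$x_of_row[i0, 2]
  # parametric hairpin: out 2 um at 45 deg up, back down 1 um, then rejoin
  t <- seq(0, 1, length.out = 120)
  px_out <- 2 / p
  path_r <- r0 - px_out * sin(pi * t)            # rises then returns
  path_c <- c0 + px_out * 2 * t                  # drifts sideways
  amp <- spec$dendrite_intensity * scale
  for (j in seq_along(t)) {
    rwin <- max(1L, floor(path_r[j] - 3 * sig_px)):
      min(nrow(img), ceiling(path_r[j] + 3 * sig_px))
    cwin <- max(1L, floor(path_c[j] - 3 * sig_px)):
      min(ncol(img), ceiling(path_c[j] + 3 * sig_px))
    d2 <- outer((rwin - path_r[j])^2, (cwin - path_c[j])^2, "+")
    img[rwin, cwin] <- pmax(img[rwin, cwin], amp * exp(-d2 / (2 * sig_px^2)))
  }
  fx$image$intensities <- pmin(img, scale)
  fx$truth$hairpin <- list(row = r0, col = c0, dendrite = 2L)
  fx
}
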