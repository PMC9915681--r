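---
title: "Quantifying CEP dendrite degeneration: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CEP dendrite degeneration: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cepscore)
```

## The measurement problem

The four cephalic (CEP) dopaminergic neurons of *C. elegans* are a standard
readout for neurotoxicity: their dendrites degenerate in a stereotyped way,
first growing bleb-like swellings ("beads on a string") and then breaking
into disconnected fragments. The conventional readout is a human looking at
each fluorescence image and assigning a 0–4 severity grade. That is slow,
coarse, and subject to drift and bias. `cepscore` replaces it with a fully
automated pipeline whose only inputs are a maximum-intensity projection of
the four CEP neurons and the camera pixel size. Every size-dependent step —
structuring elements, peak separations, probe windows, crop margins — is
specified in micrometres and converted through the calibration, which is
what makes one parameterisation portable across microscopes, objectives and
cameras.

The pipeline produces, per dendrite, 19 named metrics (`metric_schema()`)
covering length, breakage, intensity, bleb counts, bleb shape (area,
circularity, extent, eccentricity, min/max Feret calipers), and bleb
position along the dendrite, plus a 0–4 categorical score designed to be
comparable with manual grading.

## Pipeline stages and their assumptions

**Region detection.** The cell bodies are assumed to be among the brightest
structures in the frame; they are thresholded at the 99.5th intensity
percentile of a globally contrast-stretched image (1st–99.9th percentile
range mapped to full scale). The image is rotated so the dendrite axis is
vertical; the angle comes from intensity-weighted second-order central
moments with the background suppressed, so the dim dendrites steer the axis
rather than only the bright somas. Rotations below 2° are not applied:
that is the estimator's own noise floor on blebby images, and interpolating
the whole frame would blur it for no geometric gain. The frame is split at
the soma bounding box, both halves are Otsu-binarised, and the half whose
connected objects are elongated and near-vertical (major/minor axis > 4,
axis within 30° of vertical) rather than circular (circularity =
4πA/P² > 0.6) is kept. Border clutter is removed, with one deliberate
exception: elongated objects are kept even when they touch the soma-side
border, because the split line necessarily cuts through the dendrites
themselves. The crop is padded by 2 µm and flipped if needed so the
cell-body side is always at the bottom; downstream code can therefore
assume one orientation.

One worm per frame is assumed throughout; a frame with several worms will
produce a meaningless crop.

**Bleb detection.** The crop receives a local (CLAHE-style) contrast
adjustment whose clip limit falls as background noise rises — the noise
estimate is 1.4826 × the median absolute deviation of below-Otsu pixels —
followed by a 4× bilinear upsample and subtraction of a rolling-ball-style
background (grayscale opening with a 5 µm disk, computed at the original
scale and upsampled, which gives the same large-scale estimate at 1/16 the
cost). Candidate blebs are pixels above Otsu + 1.0 × noise that survive
erosion with a horizontal line of 1.5 µm (twice the expected dendrite
width): dendrites are thinner than blebs, so the strands vanish and wide
clusters remain. Each seed is refined by a two-phase Chan-Vese segmentation
(50 iterations, window 3× the seed bounding box) run on the upsampled
*raw* intensities, not the equalised ones — local equalisation pulls
dendrite brightness up to bleb level and would let the contour leak along
the strand. The scheme alternates nearest-mean classification with a
Gaussian smoothing of the indicator (the curvature surrogate) and includes
an area-penalty margin (ν = 0.15 |c₁ − c₂|) that stops the inside mean
from creeping down onto the adjacent dimmer dendrite; without it a bright
bleb slowly annexes its strand. A collapsed contour falls back to the
seed's pre-threshold component. Features smaller than 0.5 µm² (about one
dendrite cross-section) or touching the crop border (cut off, or stalk
glow at the cell-body edge) are discarded.

Feature measurement uses standard digital-geometry estimators: Kulpa-
weighted chain lengths for perimeter (digital disks come out within ~2% of
2πr), pixel-projection sweeps over 90 orientations for Feret calipers, and
second-moment eigendecomposition for eccentricity. Mean feature intensity
is sampled from the *original* crop under the downscaled mask, so contrast
adjustments never leak into reported intensities.

**Dendrite tracking.** On the local-contrast image, each pixel row
contributes up to four local maxima that exceed a prominence floor (the
larger of background median + 2 × noise and the image's Otsu level,
computed on the equalised image itself since equalisation amplifies
background noise) and are mutually ≥ 1.5 µm apart. A small isotropic
dilation restores 8-connectivity across the ±1–2 px lateral jitter of peak
positions, then a vertical closing of 4 µm bridges missing rows, and each
component is reduced to one centreline point per maximal horizontal run
per row (the skeleton of a near-vertical strand; per-run rather than
per-component so that a component transiently bridging two strands still
yields one point per strand). Points are swept from the distal end toward
the cell body and assigned one-to-one per row to the dendrite whose
exponentially weighted running-average x (memory 25 rows) is nearest,
within 3 × the minimum separation; of two points competing for one index
the farther is released. Segments supported by at least 5 rows may open
new indices (up to 8 provisional); at the end the four indices with the
longest row support are kept, renumbered left to right, and a warning is
logged if more were plausible. Tracks are interpolated linearly across
missing rows, passed through a 5-point running median (rejecting
single-row outliers), and smoothed with a 3 µm moving average.

A documented limitation is inherited deliberately: the tracker advances
monotonically along rows, so a hairpin turn of ≥ 90° is smoothed through
and interpolated rather than followed. The `hairpin` phantom asserts this
behaviour rather than "fixing" it.

**Breaks, matching, report.** For every track row, a probe window of ± one
dendrite width around the track x is tested against the Otsu-binarised
crop; rows with empty probes are break rows and maximal runs become break
intervals. Runs touching the span ends are trimmed off instead of counted:
where support stops at an extremity the dendrite simply ends there (tracks
overshoot the blurred tip by a few rows), whereas interior runs are real
breaks. `dendrite_remaining` is 1 − break rows / span rows. Blebs are
matched to the track minimising lateral distance at their centroid row
(radius 3 µm, ties to the lower index) and receive an arc position from
the cell-body end, normalised by track length. The 19 metrics then follow
directly; per-image aggregate rows are means over dendrites.

**Categorical score.** The 0–4 bins reproduce the published procedure:
more than 85% remaining with no blebs → 0, fewer than 5 blebs → 1, 5 or
more blebs → 2 (the source leaves exactly five undefined; it is assigned
to the "more" bin so the scale is exhaustive), 50–85% remaining → 3, 50%
or less → 4. The bins are evaluated in precedence order 4, 3, 0, 2, 1 so
that breakage outranks blebbing — a dendrite with 40% remaining and seven
blebs scores 4, mirroring manual grading where the breakage grades sit
above the blebbing grades. All boundaries are configuration fields.

**Statistics.** Group comparisons score each dendrite as one observation.
z-scores use the control group's own standard deviation (not pooled), so
the value reads as "how many control SDs the treatment moved"; one-way
ANOVA is the classical between/within F test; multiplicity is handled by
Bonferroni or by a many-to-one Dunnett-style comparison approximated by a
seeded permutation of the maximum |t| across treatments. The permutation
approximation was chosen over exact multivariate-t critical values to keep
the dependency surface small; the test suite cross-checks it against an
exact implementation and verifies family-wise error control on simulated
nulls.

## The phantom generator: what it emulates, and what it does not

Because the original worm images are not redistributable, validation rests
on synthetic phantoms with exact ground truth (`phantom_spec()`,
`render_phantom()`, `phantom_suite()`). A phantom renders four (optionally
five) near-vertical strands of Gaussian cross-section (σ 0.32 µm, FWHM
≈ 0.75 µm — matching the pipeline's expected dendrite width) spaced 4 µm
apart with a gentle sinusoidal wiggle (amplitude 1 µm, period 40 µm),
rising from 2 µm soma disks at 0.9 of full scale; dendrite amplitude is
0.30 of full scale over a 0.02 background. Blebs are isotropic Gaussian
bumps whose stated diameter is their FWHM (default 2 µm, twice the strand
amplitude), breaks zero out exact row intervals (so ground-truth
`remaining` is exact by construction), illumination gradients multiply a
linear plane, a 0.2 µm Gaussian PSF blurs the scene, and seeded Gaussian
camera noise is added at amplitude/SNR (default SNR 10; the stress fixture
uses 5). The default frame is 256 × 192 px at 0.325 µm/pixel — a
40×-objective-with-CMOS-camera geometry — giving dendrites about 65 µm
long, and the same physical scene can be rendered at any pixel size for
scale-covariance checks.

What the phantoms do **not** model: worm-body autofluorescence, other
neurites crossing the field, depth-dependent blur from the projection,
Poisson photon statistics, motion artifacts, or several worms per frame.
Passing the phantom suite therefore demonstrates that the algorithmic
chain is correct and calibrated on its stated geometry — not that every
real image will segment cleanly. The QC flags (too few tracks, overlapping
tracks, saturated soma threshold) exist precisely for the real-image
failure modes the phantoms cannot exercise.

The twelve-fixture suite covers: clean; sparse and dense blebbing; 20, 50
and 80% dendrite loss; combined damage; 30° and 90° rotations; a
five-strand stressor (the tracker must cap at four); a hairpin-kink probe;
and low SNR. On this suite the pipeline recovers `dendrite_remaining`
within ±0.01 of truth, track paths within ~0.2 px mean absolute deviation
(≤ 0.6 px at SNR 5), every seeded bleb within 1.5 µm of its true centre,
and zero false features on clean fixtures.

## Numerical choices and degenerate inputs

* Physical-to-pixel conversion rounds half-up and floors at 1 px so
  structuring elements never degenerate at coarse pixel sizes.
* All thresholds floor at the noise level: the "less stringent" Otsu
  binarisation adds a median + 3 × MAD floor so nearly-empty fields (80%
  loss) do not binarise their noise.
* Constant or all-zero images fail cell-body detection with a clear error;
  in a batch they become QC rows and the batch continues. Nothing is ever
  silently dropped.
* Ties are deterministic everywhere: nearest-track assignment and feature
  matching break toward the lower index; the pipeline is bitwise
  reproducible for a fixed image and configuration, and phantoms are
  bitwise reproducible for a fixed spec and seed.
* Feature-derived means are reported as missing (`NA`) when a dendrite has
  no matched features, never as zero.

## Validation problem sizes

The test suite and validation figures in this package use the fixture
sizes above (256 × 192 px phantoms; 2 000 replicates for the ANOVA type-I
calibration at n = 10 × 3 groups; 300 simulated null families at 199
permutations for the Dunnett calibration, with a 3σ binomial acceptance
band around 0.05; pixel-covariance checks at 0.1 vs 0.2 µm/pixel). These
sizes were chosen to give tight Monte-Carlo bands while keeping a full
run in the minutes range on one core. Invariance checks compare lengths,
remaining fractions and feature counts; feature *areas* are
threshold-sensitive at the few-percent level across resolutions and are
validated instead by the diameter-sweep scaling law (area quadratic,
calipers linear in bleb diameter, log–log slopes within 10%).

## Known limitations

* One worm per frame; all four dendrites should be visible. Overlapping
  dendrites are reported as breaks (and flagged by QC when tracks coincide
  for > 20% of rows).
* Hairpin turns ≥ 90° are interpolated through, as described above.
* The categorical score depends only on `dendrite_remaining` and
  `feature_count`; it is a compatibility shim for manual grading, and the
  18 continuous metrics are the intended primary output.
* Chan-Vese refinement operates on the 2-D projection; overlapping
  structures in z are merged by the projection before the pipeline ever
  sees them.
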