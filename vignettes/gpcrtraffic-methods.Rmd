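---
title: "Methods: quantifying GPCR trafficking phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GPCR trafficking phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures in `gpcrtraffic`, the
choices behind their numerical details, and what validation on the
package's synthetic data does and does not establish.

## Peripheral-membrane quantification

The measured quantity is the mean fluorescence of a receptor channel in a
morphological band at each cell's edge — a proxy for plasma-membrane
receptor abundance. The chain is:

1. **Separation erosion.** Every label in the segmentation mask is eroded
   independently with a diamond (L1-ball) structuring element of radius 1 px
   so that adjacent cell masks no longer touch. Erosion with a radius-r
   diamond is computed as r successive radius-1 erosions (the diamond is
   separable under Minkowski addition), with out-of-bounds pixels treated as
   background. This decomposition is exact and is verified in the tests
   against a brute-force L1-ball containment oracle.
2. **Size filter.** Connected components (8-connectivity) smaller than
   5000 px are discarded; survivors are relabeled 1..K. The threshold is
   meant to remove debris and partial cells at the image scale of roughly
   80-px cell diameters; it is applied after the separation erosion.
3. **Ring construction.** The peripheral ring is the cell minus its 7-px
   diamond erosion: the band of pixels within L1 depth 7 of the edge. Cells
   that the ring erosion would empty entirely (objects thinner than the
   intended cell size) are flagged and excluded from measurement rather than
   measured whole.
4. **Pseudo-flat-field subtraction.** The image minus its Gaussian blur with
   sigma = 50 px. The blur is a separable convolution truncated at 4 sigma
   with half-sample reflective boundaries; reflection avoids the dark-edge
   artifacts zero or constant padding would introduce at the field border.
   The result is signed and deliberately not clipped — clipping would bias
   dim cells upward. Because the blur operator is linear with unit row sums,
   adding a constant to the image leaves ring means exactly unchanged and
   scaling the image scales them linearly; both properties are tested.
5. **Measurement and normalization.** Per-cell arithmetic ring means,
   expressed as percentages of the control-group mean (per stratum, e.g.
   time point, when one is given), summarized with SEM and percentile
   bootstrap CIs (B = 1000 by default).

Assumptions: single-plane images; cells fully inside the frame; one label
per cell; the ring width (7 px) comfortably covers the membrane signal at
the ~80-px cell scale. Coordinates are 1-based (row, column) following R's
matrix convention; radii and sigmas are in pixels.

## Vacuole line-scan phenotyping

Confocal frames are background-corrected by rolling-ball subtraction: the
background is the grayscale opening of the image with a ball of radius
50 px (erosion then dilation with the ball's height profile), i.e. the
envelope traced by rolling the ball under the intensity surface. A flat
image maps to zero; structure narrower than the ball survives.

A line scan through the largest vacuolar body gives paired marker
(vacuole membrane, e.g. Vph1) and cargo (receptor) series. The two marker
peaks are found as strict local maxima ranked by topographic prominence
(the height above the lowest contour line enclosing no higher point), with
a minimum separation of 10 samples by default — at typical confocal
sampling of 0.043 µm/px that is ~0.4 µm, well below any resolvable
vacuole. Prominence ranking makes the choice robust to noise maxima on the
baseline without any smoothing; no smoothing is applied by default so the
measurement chain stays monotone-transparent, but the separation parameter
is configurable.

The membrane index set is the two peaks ± 1 sample (clipped at the series
ends, with fewer than six samples in that case); the lumen is the closed
range strictly inside the flanked peaks, `[left + 2, right - 2]`. The
phenotype is **full** when mean cargo in the lumen exceeds mean cargo at
the membrane (lumen:membrane ratio > 1), **empty** below 1. A ratio of
exactly 1 classifies as full: the boundary has measure zero in real data
and a deterministic tie rule is required. Cells with fewer than two
qualifying marker maxima, peaks too close to enclose a lumen, or
non-positive membrane means are flagged unclassifiable and excluded from
group fractions. Classification is invariant under profile reversal and
under positive rescaling of the cargo channel (both tested).

Peak endpoints or precomputed profiles are inputs: selecting the vacuolar
body and placing the scan is a judgment call this package does not automate.

## Hill dose-response fitting

Reporter fluorescence is divided by culture density (A600) well by well,
and per-dose replicate means are fit to

$$y(d) = b + E_{max}\,\frac{d^{\,n}}{EC_{50}^{\,n} + d^{\,n}}$$

by Levenberg–Marquardt least squares with all four parameters bounded below
by zero and unbounded above. The basal term b is required because plates
include a 0 µM column, and the model is defined at zero dose (y(0) = b).
Start values — b = min response, Emax = max − min, EC50 = the dose nearest
half-maximum, n = 1 — are robust for sigmoid data on a log-spaced ladder.
95% CIs use the asymptotic (Jacobian-based) covariance with a t quantile at
n − 4 degrees of freedom; profile-likelihood intervals are out of scope.
Fitting uses per-dose means (replicate counts are recorded; per-replicate
weighted fitting is available but off by default). Fits are flagged when
the optimizer fails, when EC50 leaves the tested dose range by more than
10×, or when the Emax interval includes zero (no response); a perfectly
flat response short-circuits to a baseline-only fit with Emax pinned at
zero. Differences between groups are called significant only when the two
95% CIs are disjoint — a conservative rule that needs no distributional
comparison of the two fits.

## Group statistics

Welch t tests (unequal variance, Welch–Satterthwaite df) for two-group
comparisons, one-tailed where the direction is pre-specified (mating).
Multi-group designs use one-way ANOVA with classic Tukey HSD (studentized
range on the pooled within-group variance). The rescue rule for a mutant
under drug is a pure function of two Tukey comparisons of the
mutant-treated group: significant only vs untreated WT = no rescue;
vs both = partial rescue; only vs treated WT = complete rescue. The
remaining cell (different from neither) is reported as *indeterminate*
rather than forced into a category. Rescue classification runs on
percent-normalized values by default (matching how such data are plotted);
raw-intensity testing is available behind a flag. Mating efficiency is the
dilution-corrected diploid percentage among mating-competent cells; an
estimate of diploids exceeding competent cells violates the design and is
an error, not a capped value.

## The synthetic-data generator

The generator produces inputs with the statistical structure the pipeline
assumes, with all ground truth recorded:

- **Fields** (default 1200×1200, 16-bit): non-overlapping axis-aligned
  elliptical cells, semi-axes uniform on 45–60 px (so every cell clears the
  5000-px filter by construction), 4-px membrane band at
  8000 × `membrane_scale` AU, cytoplasm 1000 AU, one interior vacuole disc
  (radius 0.4× the minor semi-axis, 400 AU), ≥ 3 px clearance between
  cells, 30 cells per field by default. The illumination gradient is an
  additive planar ramp (500→1500 AU) — additive so that flat-field
  subtraction can remove it, which is what that correction is for; noise is
  Poisson counting noise plus Gaussian read noise (sd 20 AU). Absolute
  intensities are arbitrary instrument units; only between-arm ratios are
  meaningful, and all recovery experiments are ratio-based.
- **Line profiles** (length 101): marker baseline 50 AU with two sd-2 px
  Gaussian peaks of amplitude 500 AU near positions 25 and 75 (±5 jitter);
  cargo at a 300-AU shoulder over the membrane positions with a lumen
  plateau at 3× (full) or 0.3× (empty) the shoulder, drawn per cell with
  the preset's empty-vacuole probability; 5% multiplicative noise.
- **Plates**: the control Hill curve (b = 50, Emax = 1000, EC50 = 1 µM,
  n = 1.2 — arbitrary anchors) scaled by the preset, on the half-log ladder
  0, 0.003, …, 300 µM, 9 replicates per dose, 10% well noise; densities
  uniform on (0.6, 0.8) multiplied into the fluorescence so normalization
  must undo them.
- **Mating counts**: Poisson competent colonies (mean 500) and binomial
  diploids at the preset's mating probability, 5 assays per arm.

Presets encode the studied relative changes (e.g. `rapamycin_ste2` has
`membrane_scale = 0.40`, `ypk1_delta` has `emax_scale = 5.33` and
`ec50_scale = 0.61`; the wild-type empty-vacuole fraction is fixed at 0.15
with the mutant at 0.60, a 4-fold change). Every generator is
deterministic under a fixed seed, with stage seeds derived from one master
seed.

**What recovery on this data does not show.** The generator makes no
attempt at photorealism: no point-spread function, no budding or
cell-cycle morphology, no multi-lobed vacuoles, no z-dimension, no
segmentation errors (masks are ground truth). Passing recovery therefore
validates the measurement and statistics chain — not robustness to
segmentation quality or optical artifacts in real micrographs.

### A known, structural bias worth understanding

The 7-px ring necessarily contains cytoplasm pixels as well as the 4-px
membrane band, and the cytoplasm level does not scale with the membrane
perturbation. Flat-field subtraction removes most, but not all, of this
additive component (it also subtracts part of the cell's own blurred
signal). The net effect is a slight compression of recovered percent
changes toward zero — a few percentage points at a 60% membrane reduction
in the analysis runs — visible in `analysis/01_quantify_pm.R` and bounded
by the recovery tests. Real measurements of this design share the same
property: the ring mean is a proxy whose contrast is diluted by whatever
non-membrane signal the band contains.

## Problem sizes and determinism

Recovery experiments use 300 cells per arm across ten 1200² fields
(peripheral quantification), 150 profiles per arm (vacuole), 9-replicate
plates (dose-response) and 5 assays per arm (mating). Because a single
pair of simulated plates leaves a few percent of sampling error in the
fitted Emax/EC50 ratio, the dose-response recovery reports the mean
recovered change over 20 independently simulated plate pairs; per-pair
values are returned so the dispersion is inspectable. The vacuole
fold-change experiment is deliberately left single-shot at 150 + 150 cells
— its sampling spread (binomial at the wild-type fraction 0.15) is part of
what such an experiment looks like.

## Limitations

- No segmentation: the package consumes label masks from any external
  segmenter and inherits their quality.
- No vendor acquisition formats; single-plane TIFF/PNG only.
- The rolling-ball implementation scales with the ball area and is meant
  for confocal-sized frames, not batch widefield processing (the widefield
  branch uses flat-field subtraction).
- Replicate pooling across imaging days is left to the caller's group
  mapping; no mixed-effects modeling is provided.
- Tukey HSD is the only multiplicity correction offered, matching the
  experimental designs the package targets.
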