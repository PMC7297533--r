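---
title: "Methods: colony-array quantification, normalisation and differential fitness"
author: "phenoplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-array quantification, normalisation and differential fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenoplate)
```

# Overview

`phenoplate` analyses high-throughput fitness screens performed on agar
plates: strains pinned in regular 96/384/1536 colony arrays, imaged on
flatbed scanners, and compared across conditions. The workflow is

1. **quantify** — colony geometry, intensity and (with a phloxine B stain)
   redness from plate images;
2. **growth** — maximum growth slopes from image time series;
3. **normalise** — per-plate spatial correction and aggregation of a whole
   experiment into one long table;
4. **qc** — plate-level quality statistics and filters;
5. **interpret** — replicate summaries and differential-fitness tests.

A synthetic-data module generates plate images, growth-curve panels and
complete multi-plate experiments with known ground truth, so that every
step above is testable without laboratory data.

# Image quantification

## Segmentation

Colonies are detected by **adaptive mean thresholding**: a pixel is
foreground when it exceeds the mean of its surrounding square block by an
offset (default 0.02). The block defaults to roughly 1.25 times the
expected lattice pitch, large enough to contain background around each
colony; it is user-overridable for unusual magnifications. The binary
image is cleaned by morphological opening (disc of radius 1) and hole
filling, then labelled. Thresholding and labelling use EBImage.

Transmission scans differ in polarity between scanner set-ups; the image
is inverted automatically when detected objects are darker than the
background (the median/mean asymmetry of the intensity distribution
decides), with an override flag.

An evenly spaced `n_rows x n_cols` lattice is then fitted to the object
centroids, separately per axis: starting from the geometric prior that the
array spans the image, objects are assigned to their nearest node and the
origin and pitch re-estimated by least squares, iterated three times.
Objects farther than half a pitch from every node are discarded; when two
objects compete for a node the larger wins and a warning is logged. This
assumes the photograph is cropped to the colony array, which is how plate
scanners in this field are operated.

The `scale` parameter (e.g. 0.1 for large scans) downsamples the image
before segmentation for speed; the mask is upsampled back, and all outputs
are reported in original-image pixel units.

## Measurements

Per grid position the records carry: **area** (pixels), **perimeter**
(corrected chain-code length with Kulpa weights 0.948/1.340 for
axial/diagonal steps, which is unbiased for smooth outlines where raw
pixel counting is not), **circularity** `4*pi*A/P^2` (capped at 1.2;
discretisation lets tiny objects slightly exceed 1), **centroid**, and
**intensity**: the sum of pixel values over the footprint minus
`area x background`, clipped at zero, where background is the median of
all off-colony pixels. The off-colony median is robust to how much of the
plate the colonies cover, which matters when the same estimator is used
across a growing time series. Intensity reflects colony thickness as well
as area, but scales non-linearly with cell number; no absolute cell-count
calibration is attempted.

## Timecourse mode

Positions are segmented in the **last** image only (where colonies are
largest), and that fixed footprint is applied to every earlier frame. The
background is re-estimated per frame, so uniform exposure drifts cancel.
Values are background-subtracted footprint sums, clipped at zero; columns
are named `R-C` with 0-based row/column.

## Redness (viability) scores

Phloxine B accumulates in dead cells, so colonies with more dead cells
look redder on a reflective colour scan. Detection runs on a
contrast-stretched mean-channel image with the same local-threshold
pipeline. The score itself is the mean over the colony footprint of the
per-pixel **chromaticity** `R / (R + G + B)`, computed on the raw loaded
channels: 1/3 for any grey pixel, larger the greater the red share, and
invariant to exposure scaling — appropriate for reflective scans whose
absolute levels vary between scanners. Contrast enhancement and
background subtraction are deliberately confined to the detection step:
applying a per-channel rescale to the scored values would make the score
depend on the plate's dynamic range (a uniformly coloured colony could
even rescale to zero in all channels), destroying comparability between
plates. Within-colony spatial redness patterns are not captured.

# Growth-curve parameters

Growth curves (background-subtracted intensity sums, or areas, per
timepoint) are summarised **non-parametrically**: an ordinary
least-squares line is fitted to every window of `fitrange` consecutive
points and the steepest window wins. Reported are the maximum slope, the
winning window's midpoint time and R², the initial and final levels
(means of the first and last `fitrange` points), and a lag estimate —
where the winning regression line crosses the initial level, clipped at
zero and flagged undefined when the slope is non-positive or the crossing
precedes the first timepoint by more than one sampling interval. No
logistic/Gompertz model is assumed, so atypical curve shapes (diauxie,
early plateaus) do not bias the estimate.

Defaults: `fitrange = 12`, matching twelve 20-min frames (4 h) of a
typical 48 h acquisition; no smoothing (an optional rolling median,
window 3, is available for noisy series). Windows containing missing
points are skipped, never imputed. Slopes are fitted on the raw proxy
scale, consistent with reporting mean differences of intensity sums per
unit time; log-scale fitting would estimate a relative rate instead and
is intentionally not the default.

On the synthetic panels used in the tests (1536 logistic curves, 5%
multiplicative noise, 20-min sampling over 48 h), the median relative
error of the recovered maximum slope at `fitrange = 12` is under 10%, and
recovered slopes rank-correlate with the generating `rK/4` above 0.95.

# Spatial normalisation

## Reference-grid surface

A control ("grid") strain pinned at known positions defines the expected
local colony size. The 384-format layout places the 96 grid in the
top-left of every 2x2 block; in 1536 format the generator spreads the 96
grid positions as evenly as 8 x 12 indices allow across the 32 x 48
array, so that **every border row and column contains grid colonies** and
no position extrapolates far beyond the grid hull. Custom layouts are
read from CSV.

The surface is built in three steps:

1. **Denoising.** Each grid value is replaced by the value, at its own
   position, of a least-squares plane fitted through the grid colonies
   within one grid-node step in each direction (an order-1
   Savitzky–Golay filter on the grid lattice). Without this, the surface
   interpolates every grid colony's measurement error exactly, and that
   error propagates to all surrounding test colonies — spatially
   correlated patches appear in the corrected values and inflate the
   neighbour-sum bias statistic. The plane fit suppresses roughly 90% of
   single-colony noise variance while reproducing **any affine trend
   exactly**, including at plate borders where symmetric filters would
   bias. Wider windows reduce noise further but mis-track the curvature
   of realistic gradients; window 1 is the default and is exposed.
2. **Interpolation.** Separable piecewise-linear interpolation: along
   columns within each grid row, then across grid rows for every column.
   Exact for planes, and matched to the lattice structure of grid
   layouts.
3. **Extrapolation.** Beyond the outermost grid nodes the edge linear
   pieces are extended (linear, not constant-value, extrapolation). This
   keeps the key identity exact: a plate whose colonies all lie on one
   affine surface self-normalises to relative fitness 1.0 at every
   position, including the border rows/columns outside the grid hull.

Grid colonies that are missing or non-positive are excluded and flagged
("missing grid colony"); at least 3 usable, non-collinear grid values are
required. Positions whose interpolated expectation is non-positive are
flagged as artefacts and their corrected values set missing. Corrected
fitness is `raw / expected`; 1 means "grows like the grid strain here".

## Row/column median normalisation

Each value is divided by its row median, then by the recomputed column
median (row first; the order is recorded in the output's
`normalisation_method`). This assumes most strains per row/column are
phenotypically neutral — true for knock-out collections, not for plates
of uniformly sick strains. It is also the documented remedy for the
secondary edge effect of grid normalisation: grid colonies next to fast-
or slow-growing neighbours are themselves perturbed by nutrient
competition, which biases the surface in the next inward row/column; a
subsequent median pass removes that residual row/column structure. When
both normalisations are requested, grid correction runs first.

A single row-then-column pass is exactly idempotent on pure
multiplicative row x column effects; on general matrices repeated
application contracts towards a fixed point but one pass is the defined
(and applied) operation.

## Aggregation

An experimental design table (one CSV row per plate: `plate_id`,
`data_path`, optional `layout_path`, `condition`, `control`, `batch`,
arbitrary metadata) drives the aggregation. Zero raw values are set
missing before normalisation (a zero-sized colony is a pinning failure,
not a measurement). Every colony becomes one row of the long output
table, with raw, reference and corrected values, the normalisation
method, and `qc_flags` explaining every value that went missing; missing
values never silently decrease. Grid colonies stay in the table (flagged
`is_grid`) so control statistics remain computable downstream, but are
excluded from differential testing.

# Quality control

* **CV** — sample standard deviation over mean of the control (grid)
  colonies; precision of the plate's readout.
* **FUV** — sample variance of controls over sample variance of all
  colonies; noise relative to biological signal. Sample (n-1) moments
  are used throughout.
* **Neighbour-sum bias** — Pearson correlation between each interior
  colony's value and the sum of its 8 neighbours (border positions are
  excluded rather than renormalised, keeping the statistic comparable
  across plates). Positive values indicate regional plate effects;
  negative values would indicate competition artefacts. On simulated
  gradient plates the raw statistic exceeds 0.5 and falls to |r| <= 0.1
  after grid correction, without ever turning significantly negative —
  the correction does not manufacture competition-like signal.
* **Timepoint correlation matrices** — Pearson correlations between
  strain-averaged value vectors at different timepoints; constant
  timepoints are flagged and their correlations set missing.

The quality filter blanks colonies with zero size or circularity below
0.85 and removes whole plates whose control CV exceeds 0.2 or whose FUV
exceeds 1 (all cutoffs exposed). Colony-level filtering happens first;
plate statistics are computed on the filtered values. Surviving values
are never altered.

# Differential fitness

Replicate colonies are the test unit; no pre-averaging. Two axes:

* **across conditions** (recommended for condition screens): each
  (strain, condition) replicate set against the same strain in the
  control condition;
* **within condition**: each strain against the pooled other non-grid
  strains of the same condition.

The default test is the **pooled-variance Student t-test**. The choice is
deliberate: screens typically run 3 biological replicates, and at n = 3
Welch's unequal-variance test is markedly conservative (its empirical
size at nominal 0.05 is near 0.03), which costs power without protecting
anything in this setting — replicate variances within a screen are
comparable by design. The pooled test has exact size under the null at
these replicate numbers; Welch and a Wilcoxon rank-sum alternative remain
available via `test=`. Effect size is reported as the **ratio of
medians** (condition/control), on the same relative-fitness scale as the
corrected values.

P-values are corrected by Benjamini–Hochberg across all contrasts of one
invocation — a screen is a single discovery exercise — with a
per-condition option. Contrasts with fewer than two replicates on either
side are skipped with a recorded reason. Under a fully null simulated
screen (238 strains x 70 conditions x 3 replicates) the raw p < 0.05
fraction is 5% +/- 1%; in a spiked screen (10 of 210 strains shifted by
3 SD, n = 6) BH at 0.05 recovers at least 80% of spiked strains with at
most 2 false positives on average.

# The synthetic-data generator

`sim_config()` fixes the study conditions; all generators are pure
functions of it (identical config, identical output).

* **Endpoint plates** — `value = base x strain effect x gradient x
  noise`. The spatial gradient is a separable cosine surface scaled to a
  peak-to-trough amplitude (default 0.4): smooth and low-order, like the
  temperature/moisture/nutrient gradients that cause real plate effects.
  Noise is lognormal with a CV parameter (default 5%): colony sizes are
  positive and their dispersion scales with their magnitude, so
  multiplicative noise is the natural model. Strain effects for screen
  simulations are drawn lognormal with sdlog 0.1
  (`random_strain_effects()`), a realistic library fitness spread.
* **Plate images** — anti-aliased disks at the lattice positions, radius
  proportional to the square root of size; an ellipse-axis-ratio knob
  produces low-circularity shapes for testing the shape filter. In RGB
  mode each colony's colour mixes a pale colony tone with a red stain
  tone in proportion to its strain's dead-cell fraction, emulating
  phloxine B.
* **Growth panels** — logistic curves `K / (1 + exp(-r (t - t0)))` with
  per-position rates drawn from N(0.5, 0.1^2) per hour; both r and K
  scale with the strain effect and gradient (less fit strains grow
  slower *and* plateau smaller, as colony-size proxies do — with a
  shared K the endpoint would carry no strain signal, which is not how
  colonies behave). Sampling defaults to every 20 min for 48 h (145
  timepoints).
* **Experiments** — replicate plates per condition written to disk as
  quantifier-dialect CSVs plus layout and design-table files, with
  condition-specific effect multipliers; the analyse → qc → interpret
  pipeline runs on the output unmodified.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: nutrient competition
between neighbours (and hence the secondary edge effect), within-colony
texture and redness structure, non-linear pixel-to-biomass response,
scanner vignetting or colour management, condition-dependent noise.

# Numerical choices and degenerate inputs

* Windows with constant time are a singular-fit error; strictly
  increasing timestamps are required throughout.
* R² is defined as 1 for exact fits of degenerate (zero-variance)
  windows, and clamped to [0, 1].
* Equal-distance lattice ties go to the larger object, logged.
* Chromaticity of a zero-sum pixel (R+G+B = 0) is excluded from the
  colony mean rather than defined arbitrarily.
* Zero row/column medians abort median normalisation with the offending
  index; all-missing rows/columns propagate missingness.
* Degenerate reference grids (< 3 usable values, or collinear) are an
  error rather than a silently flat surface.
* CV with mean 0 and FUV with zero total variance are errors, not NaNs.
* Test statistics on two constant, equal groups give p = 1; constant,
  unequal groups are reported as undefined with a reason, matching what
  `t.test()` would refuse to compute.

# Problem sizes in the test suite

The suite exercises the full 1536 format where the property under test
concerns scale (full-plate detection, slope recovery on 1536 curves,
neighbour-bias removal on 32 x 48 plates across 5 seeded replicates);
statistical calibration uses 238 strains x 70 conditions x 3 replicates
over 10 seeds and 100 spiked-screen repetitions; pipeline recovery uses
238 strains in 384 format with 6 replicate plates x 3 conditions, enough
replicates that replicate sampling noise does not mask pipeline fidelity.

# Known limitations

* The lattice fitter assumes images cropped to the array; plates
  photographed with wide margins need pre-cropping.
* The reference surface cannot distinguish a genuine biological gradient
  from a technical one; it removes both.
* With very sparse plates (most positions empty) the lattice fit relies
  on the geometric prior and may mis-assign single outlying colonies.
* Redness scores are relative within an experiment; no absolute
  dead-fraction calibration is provided.
* Colony-level variance moderation (empirical Bayes) and strain x
  condition interaction models are out of scope.
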