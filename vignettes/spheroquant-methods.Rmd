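---
title: "spheroquant: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spheroquant: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroquant)
```

`spheroquant` quantifies multicellular tumor spheroids imaged in hydrogel
microchamber (MC) arrays. Because each chamber holds at most one spheroid
and walls keep it in place, the chamber index is a persistent identity:
the same object can be measured before and after a treatment, which is what
makes per-spheroid (rather than population-average) statistics possible.
This vignette is the package's account of the models it implements, the
parameters that matter, and what its validation on synthetic data does and
does not establish.

## Segmentation

Spheroids are detected on the bright-field plane as closed regions of high
Sobel gradient magnitude. The pipeline in `segment_field()` is

1. Sobel gradient magnitude (3×3 kernels, replicate boundary);
2. Otsu threshold on the normalized gradient (the classical choice when no
   threshold is given a priori);
3. morphological closing with a disc of radius `close_radius` (default
   3 px) to seal dashed edges;
4. hole filling;
5. per-component outline refinement (below);
6. connected-component labelling, keeping components with physical area in
   `[min_area, max_area]` (defaults 500–60 000 µm², generous brackets
   around plausible spheroid sections).

**Why the refinement step.** The gradient of a step edge is high on *both*
sides of the true boundary, so the filled edge components overshoot the
object by roughly the half-width of the gradient band (~1 px on each side).
Measured against the generator's ground truth, raw filled components
overestimate area by ~9%, and compensating with a fixed 1-px erosion
overshoots the other way (~−4%): whole-pixel morphology cannot remove half
a band. Since per-ROI area feeds directly into growth ratios and cell
counts, a percent-level bias matters. `segment_field()` therefore re-draws
each component's outline by Otsu thresholding the *intensity* in the
component's padded bounding box, taking the darker side as the object
(spheroids are darker than the bright background) and re-filling holes.
Edges locate the objects; intensity draws the outline. This brings area
errors below ~1.5% on synthetic fields. `refine = "none"` restores the raw
edge-only pipeline for comparison.

Coordinates follow the pixel-center convention: pixel `(i, j)` (1-based)
sits at `((j − 0.5)·s, (i − 0.5)·s)` µm for pixel size `s`. ROIs touching
the field border are kept but flagged. Chamber assignment
(`assign_chambers()`) is centroid containment in the grid cell; a centroid
exactly on a cell boundary resolves to the lower (row, col) index, a
deterministic tie-break. Tracking (`track_rois()`) pairs ROIs with the same
chamber index; a chamber with two ROIs at one timepoint is flagged
ambiguous and excluded rather than guessed at.

## Fluorescence quantification

Background is the mean of the pixels *between* the outlined ROIs, estimated
independently for every acquired plane (`estimate_background()`); it is
never shared across planes, because illumination and staining vary plane to
plane. Metrics (`measure_roi()`) are computed on background-subtracted
intensities with negative residuals clipped at 0:

* `mean_fi` — mean of ROI pixels at/above the positivity threshold;
* `area_fraction` — percent of ROI pixels at/above it;
* `pixel_cv` — sd/mean of all (unthresholded) ROI pixels, the
  within-spheroid staining heterogeneity (the TMRM CV statistic).

The positivity threshold is applied *after* background subtraction, which
makes every metric exactly invariant to a constant offset added to a plane.
Its default is 2× the background pixel sd (`default_threshold()`): the
smallest round multiple that excludes essentially all background noise
under the Gaussian noise model; it is a tunable in background-subtracted
intensity units.

`tmrm_ratio()` is the per-spheroid FI ratio between two timepoints, defined
only when the first FI is positive (flagged otherwise). Cutoff rules
(`make_cutoff()`) are `mean ± sample SD` (n−1 denominator throughout the
package) of a control population; classification (`classify_positive()`,
`classify_growth()`) uses strict inequalities at the cutoffs, so a value
exactly at a cutoff is *not* positive/HP — the boundary case had to be
decided one way and strictness is conservative. `staining_homogeneity()` is
the CV of per-focal-plane mean FI across a z-stack, with a QC limit
defaulting to 0.08.

## Morphometry

Sphericity is the moment-based roundness
`S = m00² / (2π(µ20 + µ02))` with `m00` the mask area and `µ20`, `µ02` its
second central moments in pixel units. For a continuous disk `S = 1`; for
an ellipse with semi-axes `a ≥ b`, `S = 2ab/(a² + b²)`, decreasing
monotonically with elongation; line-like masks give `S` near 0 and are
flagged degenerate. Rasterization perturbs `S` by well under 2% for radii
≥ 10 px (the pixel-quantization correction to the second moments is
`n/12` per axis, negligible at these sizes). Texture is the Shannon entropy
(natural log) of the ROI's gray-level histogram over 64 equal-width bins
spanning the ROI's own min–max, plus the pixel SD and range. Because the
binning adapts to each ROI's range, entropy values are comparative between
ROIs analysed with the same bin count, not absolute information measures;
constant ROIs return (0, 0, 0) by convention.

Physical estimates assume spheres: a cell's volume from its projected area
(`r = √(A/π)`, `V = 4/3·πr³`, in pL), a spheroid's sphere-equivalent volume
from its sectional area, `N = round(V_sph / V_cell)` cells (minimum 1), and
doubling time `Td = dt·ln2/ln(N2/N1)`, defined only for growing
populations. The sphere assumption is the natural closure when only one
section per object is available, and it reproduces the published worked
examples (4900 µm² at 1.69 pL → 153 cells vs 154 printed; 4880 µm² at
2.79 pL → 92 vs 94) within 2.5%.

## Growth subpopulations

`growth_ratio()` is `GR = A(after)/A(before)` with percent change
`100·(GR − 1)`. HP/mid/LP classes come from a control-derived cutoff rule;
with a control GR population of mean 1.23 and SD 0.20 the cutoffs fall at
1.43 and 1.03. `kmeans_cluster()` z-scores features before clustering —
growth ratios (~1) and fluorescence intensities (~1–15 au) differ by an
order of magnitude, and unscaled k-means would cluster on intensity alone —
then runs `stats::kmeans` (Hartigan–Wong) with 10 random starts under a
fixed seed, default `k = 3` for the three proliferation subgroups. Labels
are renumbered by ascending center on the first feature so that identical
inputs always yield identical labellings; `k = n` is handled as the forced
singleton partition.

## Invasion

Migration distance is the Euclidean centroid displacement between two
tracked timepoints, in µm. Shape change during invasion (flattening) is
reported through the sphericity metric rather than a dedicated statistic.
`invasion_summary()` gives per-condition mean/SD/n, fixed-width histograms
(default 25 µm bins) and, for two conditions, a rank-sum comparison —
migration distances are non-negative and right-skewed, so a nonparametric
default is appropriate.

## NO-donor kinetics

A NONOate donor decays exponentially, `D(t) = D0·2^(−t/t½)` (t½ = 24 h and
ν = 2 mol NO per mol donor for DETA/NO at pH 7.4, 37 °C), releasing
`ν·(D0 − D(t))` NO cumulatively. Free NO is consumed by medium and cells;
modelling consumption as a single first-order sink with rate `k_c` gives
the quasi-steady concentration `[NO]ss = ν·k_d·D0/k_c`, `k_d = ln2/t½`,
exactly linear in the dose. `k_c` has no mechanistic derivation here — it
absorbs everything that removes NO — and is calibrated from one measured
reference pair via `calibrate_kc()` (100 µM donor ↦ 100 nM NO), after
which the model predicts 1 nM at 1 µM exactly. The quasi-steady
approximation treats the release rate as constant, valid for exposure
times short relative to the half-life; over a 24 h exposure at t½ = 24 h
the release rate halves, so late-exposure concentrations are overestimated
by up to ~2×. The model is a dose-scaling tool, not a kinetic simulation.

## Statistics and reporting

`compare_groups()` wraps the standard designs (Welch t, paired t, one-way
ANOVA, Wilcoxon, Kruskal–Wallis). With `design = NULL` it picks a
nonparametric test when any group has n < 20 — small per-condition spheroid
counts are common and normality is not auto-tested. Identical degenerate
groups return statistic 0 and p = 1 instead of erroring. P-values are
reported unadjusted and labelled as such; no multiple-testing correction is
applied, so users comparing many metrics should correct downstream.

## The synthetic generator, and what the tests show

`simulate_array()` renders spheroids as filled ellipses on a regular
chamber grid: bright background (30 000 au), dark 4 µm rim (8 000 au),
mid-gray textured interior (18 000 au ± `texture_sd`), additive Gaussian
noise clipped to [0, 65535], written as 16-bit. The defaults are the study
conditions the pipeline targets: day-2 sectional areas N(4900, 2450²) µm²
truncated at 350 µm² (the Gaussian puts ~3% of its mass below any
physically plausible spheroid; truncation by rejection shifts the realized
mean by about +150 µm², which the moment-matching tests account for),
control growth ratios N(1.23, 0.20²), axis ratios 1 ("round" phenotype;
down to ~0.2–0.6 for "rough"/elongated populations), 2 µm/px so typical
spheroids span ~40 px. Pixel size has no universal default in array
imaging, so it is an explicit config input. Fluorescence channels follow
three signal models — a positive-pixel *fraction* (apoptosis-marker-like),
a *graded* whole-spheroid intensity (receptor/probe-like), and a
two-timepoint multiplicative *ratio* (potentiometric-dye-like, factor
N(1.72, 0.61²) truncated at 0.1). Invasion mode displaces each spheroid by
independent N(0, σ²) components, i.e. Rayleigh(σ) distances with mean
σ√(π/2); displacements leaving the field are clipped and flagged. One RNG
is seeded per simulation and consumed in a documented fixed order, so
identical configs are bit-identical; configurations whose sampled spheroids
cannot fit their chambers are rejected with a sizing error rather than
silently clipped.

The generator emulates the *statistical* structure of array acquisitions —
population moments, mixtures, signal fractions, displacements — with full
ground truth. It deliberately does not model optics (defocus, shading,
vignetting), cell-scale interior structure, touching or out-of-chamber
spheroids, or z-resolved imaging (z-stacks enter only as per-plane mean
vectors). Passing tests therefore establish correctness of the measurement
definitions and recovery under the stated contrast/noise/size conditions;
they do not certify segmentation performance on real optics, where contrast
and focus vary. On real data the edge pipeline's parameters
(`close_radius`, `min_area`/`max_area`, the threshold multiple) are the
knobs to revisit.

Problem sizes in the test suite are chosen to exercise the claims at
meaningful scale while staying quick: 3×3 arrays (9 spheroids) for
per-object accuracy, a 15×14 fully occupied array (210 spheroids, two
timepoints) for population moments and end-to-end recovery, n = 400 for
cutoff/mixture sampling (the control-population size the cutoffs are
defined on), and a 2 mm-pitch field rendered at 16 µm/px for the Rayleigh
displacement moments (coarse rendering keeps a 210-spheroid invasion field
around two megapixels; only the truth table is consumed there).

## Numerical conventions

* Sample SD (n−1) everywhere, including cutoffs and CVs.
* Strict inequalities at all cutoffs; ties at chamber boundaries resolve to
  the lower index.
* Truth CSVs are written with 17 significant digits and round-trip
  double-precision exactly; TIFFs are 16-bit, so image round-trips are
  exact to one gray level.
* Constant/blank planes segment to an empty ROI set; constant ROIs have
  zero entropy/SD/range; empty masks, non-positive areas, unpaired ROIs and
  uncalibrated models raise errors rather than returning silent defaults.

## Known limitations

* The sphere-equivalent cell count inherits the sphere assumption; for
  flattened (invading) spheroids it overestimates volume.
* Entropy depends on the bin count and per-ROI range; compare only within
  one analysis configuration.
* Chamber-based tracking assumes spheroids stay in their chambers; in
  invasion mode it remains valid only while displacements are small
  relative to the chamber pitch, as in the bundled invasion tests.
* The NO model's single-sink consumption is a calibration device; it has
  no predictive power outside the dose range anchored by the reference
  pair.
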