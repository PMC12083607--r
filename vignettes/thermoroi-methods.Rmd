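---
title: "Methods: thermal ROI analysis of induced skin cooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal ROI analysis of induced skin cooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoroi)
```

`thermoroi` analyses a controlled skin-cooling experiment: a cold stimulus
is applied over the posterior superior iliac spine, and paired
optical/thermal images taken under a factorial set of imaging conditions
are reduced to per-image median temperatures and modelled against camera,
environment, and skin-tone factors. This vignette records the models, the
numerical conventions, and the design decisions that were genuinely open,
so that a maintainer can see why the code is the way it is.

## Colorimetric calibration

Two colorimeters report skin melanin on different scales. The bridge is the
log-linear calibration

$$y = \exp\!\left(\frac{x + c_\mathrm{offset}}{c_\mathrm{scale}}\right),$$

with $x$ the SkinColorCatch melanin index and $y$ the ColorMeter-scale
value on which the modified Eumelanin categories are defined (bounds 25,
37.5, 50, 75, 100). The shipped default constants are 623.18 and 334.81;
`fit_calibration()` re-estimates them from swatch pairs by ordinary least
squares of $\log y$ on $x$, the regression matching the functional form, so
$R^2$ is reported on the log scale. Triplicate swatch readings are averaged
first (`average_swatches()`).

Two conventions are worth stating. Category intervals are lower-inclusive
(`[25, 37.5)`, ...), applied uniformly at every boundary, so a value of
exactly 37.5 is `intermediate`. And the calibration demands a positive
fitted slope: the conversion must be strictly increasing, and a
non-increasing fit is reported as an input error rather than silently
returned.

An ambiguity we deliberately did not resolve: the cohort summary the
generator emulates (melanin 55.94 ± 13.54) is not self-consistent with
running that value through the calibration — converted values would fall
far below the Intermediate-Mid band where most of the cohort sits.
`generate_cohort()` therefore draws melanin directly on the classification
scale, which reproduces the reported category composition; the
`melanin_index_scc` path through `add_skin_tone()` exists for genuinely raw
device readings.

## Registration

Fiducial card corners are annotated in both frames and a full 6-parameter
affine map is estimated by least squares (`estimate_affine()`); with three
non-collinear pairs it interpolates exactly, with more it minimises the
summed squared target residual (the contract is the minimiser, not the
algorithm — the QR solve is an implementation detail). Residual RMS is
exposed (`affine_rms()`, and as an attribute) so callers can impose a
quality threshold; no specific threshold is baked in because none is
established for this protocol.

All modules share one pixel convention: 0-based `(col, row)` coordinates,
origin at the top-left pixel center, rows increasing downward. Annotations
digitized on the optical image are warped into the thermal frame
(`warp_annotations()`) instead of resampling the thermal image, so
temperatures are never interpolated; `resample_affine()` (bilinear) exists
for visual overlays only.

## ROI geometry

**Ellipse fitting.** With only five boundary clicks an unconstrained conic
fit can return a hyperbola, so `fit_ellipse()` uses the direct algebraic
least-squares fit with the ellipse constraint $4AC - B^2 = 1$, in the
numerically stable partitioned (scatter-matrix) formulation, with input
points centered first. Noiseless samples of a true ellipse are recovered to
better than 1e-6; collinear or insufficient points raise a fit error, as
does a degenerate conic.

**Control region.** The control ellipse copies the ROI rotation with both
semi-axes scaled by exactly 1/4, displaced from the ROI center along the
image column axis by $d = w_\mathrm{control} + a_\mathrm{ROI}$, where
$w_\mathrm{control}$ is the control ellipse's full extent along the
displacement axis and $a_\mathrm{ROI}$ the ROI semi-major axis. Two
readings of the offset rule's "width of the ellipse" are possible; we take
the control ellipse (the sentence's nearest antecedent) as the default and
keep the cooling-ROI reading behind `width_rule = "roi"` for sensitivity
checks. The displacement axis is fixed by the protocol ("superior along the
x-axis") but its sign depends on left/right framing, so it is a config flag
with default `c(-1, 0)`.

**Relocation.** Manual relocation of a colliding control region is replaced
by a deterministic search: candidate centers on expanding rings (1 px
radial step, 32 angular steps), accepting the first ring with a valid
position and, within a ring, the candidate with the smallest angular
deviation from the default displacement direction (positive deviation wins
exact ties). Valid means: fully inside the image, rasterized mask disjoint
from both the ROI mask and the exclusion mask. Reproducibility is the
point; the tests verify the accepted position against a brute-force
nearest-valid-grid-center oracle.

**Rasterization and medians.** A pixel belongs to a region iff its center
satisfies the ellipse interior inequality — the same rule in the
implementation and in every test oracle. The even-count median is the mean
of the two central order statistics; this is stated explicitly because it
affects bit-level reproducibility of the observation table. The full
fitted ellipse interior is used; marker-ink pixels are not excluded, as
nothing in the protocol specifies that they were.

## Statistical models

The long observation table has one row per image and region. Three
fixed-effect structures are fitted with a participant random intercept by
REML, with Satterthwaite p-values:

* **camera:** `median_temp_c ~ period * camera`, on absolute ROI
  temperature or on the per-image ROI − control difference;
* **environment** (reference camera only): `period + distance + lighting +
  posture + period:distance`, with optional `period:lighting` /
  `period:posture` interactions — both one-model and separate-assessment
  readings of the protocol are supported via the `interactions` argument;
* **melanin:** `period * melanin_c`, melanin continuous and centered at
  the cohort mean so the `period` coefficient is the cooling effect at
  average skin tone.

Treatment coding with reference levels E8XT / baseline / 35 cm / ambient /
knees-stacked makes each printed coefficient a single interpretable
contrast. The single random intercept is the simplest structure consistent
with the repeated-measures design; a participant-by-camera intercept can be
requested through the `random` argument for sensitivity analysis. On
difference responses the participant intercept cancels and the variance
component legitimately hits zero; such boundary (singular) fits are
reported as converged. Missing cells are handled by fitting the available
rows; there is no imputation. `category_effect()` converts a fitted
cooling-by-melanin slope into degrees per skin-tone category (25 melanin
units per category).

The descriptive summary (`summarize_cooling()`) reports per-region baseline
and cooled means ± SD, the within-region change (cooled − baseline) tested
against zero by a one-sample *t*-test, and ROI-vs-control paired *t*-tests
at each period. A zero-variance change vector (the exactly-null case) is
reported as statistic 0, p = 1 rather than an error.

## The synthetic generator

The generator is the analysts' model run forward. For the ROI,

$$T = \beta_0 + u_i + \beta_\mathrm{cam}\,\mathrm{ProOne}
 + \beta_\mathrm{cool}\,\mathrm{cooled}
 + \beta_{\mathrm{cool}\times\mathrm{cam}}\,\mathrm{cooled}\cdot\mathrm{ProOne}
 + \beta_{d50}\,d_{50} + \beta_{\mathrm{cool}\times d}\,\mathrm{cooled}\cdot d_{50}
 + \beta_{\mathrm{cool}\times\mathrm{mel}}\,\mathrm{cooled}\cdot(\mathrm{mel}-\bar{\mathrm{mel}})
 + \varepsilon,$$

with $u_i \sim N(0, 1.7^2)$ and $\varepsilon \sim N(0, 0.9^2)$ (°C). The
control region shares the baseline terms, sits 0.3 °C above the ROI at
baseline, and under cooling receives only a small drift (−0.2 °C) plus its
own cooling-by-camera interaction. Fixed-effect defaults are the published
coefficients (−4.19 cooling, −2.43 camera offset, +1.89 cooling×camera on
absolute ROI temperature, −0.11 distance, +0.20 cooling×distance, −0.013
°C/unit cooling×melanin; lighting and posture null but configurable to test
detection).

Three generator choices deserve explanation:

* **Control-region camera interaction (+0.85 °C).** The reported
  cooling-by-camera interaction is 1.89 °C on absolute ROI temperature but
  1.04 °C on the ROI − control difference; both can only hold if the
  control region itself carries a 0.85 °C interaction, so the generator
  includes one. It is configurable (`beta_cooled_x_camera_control`).
* **Pooled baseline mean.** `baseline_roi_mean` (30.8 °C) is interpreted
  as the design-pooled baseline ROI mean — the quantity a summary table
  reports — not as the reference-cell intercept. The intercept is derived
  by removing the average camera/distance/lighting/posture contribution,
  so simulated cohorts reproduce the pooled mean in expectation while
  every coefficient stays exact.
* **Variance components.** Between-participant (1.7 °C) and residual
  (0.9 °C) SDs are calibrated so simulated summary-table SDs land near the
  reported 2.0/1.7/1.2 °C values; they are conventions, not published
  quantities, and are documented as such.

Because the camera and melanin models omit the distance terms, their
cooling coefficients estimate *marginal* (design-averaged) combinations of
the generative betas under the balanced design; `expected_effects()`
returns these closed-form estimands, and all parameter-recovery tests
compare fitted coefficients against them rather than against the raw
configuration values.

Image fixtures render an optical frame (skin background, dark marker ring,
light fiducial card) and a thermal frame (background minus a Gaussian cold
spot centered on the marker, plus i.i.d. Gaussian pixel noise, 0.1 °C
default), along with fiducial correspondences and jittered boundary clicks
(0.2 px SD). What the fixtures do *not* emulate: spatially correlated
sensor noise, tissue heat diffusion and rewarming dynamics, anatomical
shape, lens distortion, or real annotation behaviour. Passing end-to-end
tests therefore demonstrate the geometry and bookkeeping of the pipeline,
not robustness to real-camera artefacts. The cold-spot contrast in rendered
bundles is governed by the cold-spot parameters, not by the observation
table, so image-mode runs validate geometry while tabular-mode runs carry
the study's statistical structure.

## Problem sizes and determinism

Every generator is a pure function of (config, seed). The test suite uses a
full-size cohort (n = 35, 1680 image rows) for calibration checks, 20
simulated cohorts for coefficient-recovery means (40 for the environment
model, whose interaction contrast has the largest Monte-Carlo variance),
1000 two-participant null cohorts for the type-I-error check of the
one-sample *t* (accepted band 3–7% at α = 0.05), and 2–5-participant
bundles with 60×80-pixel thermal frames for the image-mode pipeline tests.
Monte-Carlo acceptance bands are expressed in Monte-Carlo standard errors
of the quantity under test, computed with participant-level clustering
where the statistic is a cohort mean.

## Known limitations

* Fiducial detection and circle detection are out of scope: annotation
  clicks are inputs. Registration quality is only as good as the
  correspondences.
* The relocation search reproduces *a* nearest-valid placement under a
  stated metric; a human operator's "nearest appropriate location" may
  differ.
* Real radiometric file formats (FLIR radiometric JPEG, MSX fusion) are
  not decoded; the supported dialects are a Celsius CSV matrix and a
  centi-Kelvin 16-bit TIFF. This is a documented extension point.
* The melanin model takes the melanin column as given; whether a "color
  unit" is a raw or converted device unit is ambiguous upstream, and the
  package does not decide it.
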