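---
title: "Normative nonlinear color look-up tables for FA maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative nonlinear color look-up tables for FA maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falut)
```

## The problem

Fractional anisotropy (FA) is a scalar invariant of the diffusion tensor,
bounded in [0, 1]. Pathological FA changes are often small and hard to see on
a gray or linearly color-mapped FA image. `falut` implements a *nonlinear*
color look-up table whose color anchors sit at normative statistics of FA in
reference brain structures, so that a trained reader can spot a structure
whose color departs from the normal range on plain inspection — for example
the middle cerebellar peduncles (MCP) in multiple system atrophy (MSA), where
FA is markedly reduced while it is normal in Parkinson disease.

## The normative model

Each subject contributes several ROI measurements to each ROI group (e.g.
six basal-ganglia circular ROIs). These are dependent repeat observations of
the group, so a random-intercept linear mixed model is fitted per group:

$$y_{ij} = \mu + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, \tau^2), \quad \varepsilon_{ij} \sim N(0, \sigma^2),$$

where $i$ indexes subjects and $j$ repeated ROIs. `fit_random_intercept()`
estimates $(\mu, \tau^2, \sigma^2)$ by REML (through `lme4`) or by the
closed-form one-way ANOVA moment estimators ($\hat\sigma^2$ = within-subject
mean square; $\hat\tau^2 = \max(0, (\mathrm{MSB} - \mathrm{MSE})/\tilde k)$
with $\tilde k = (N - \sum_i n_i^2/N)/(m-1)$ the imbalance-adjusted
per-subject count). On balanced designs with interior estimates the two
routes coincide, which the test suite uses as a cross-check; REML is the
default because it handles imbalance natively. Negative moment estimates of
$\tau^2$ are truncated at zero so the prediction interval stays defined.

### The prediction interval

The LUT anchors use the 95% *prediction* interval for a single new
observation on a new subject:

$$\hat\mu \pm z_{0.975}\,\sqrt{\hat\tau^2 + \hat\sigma^2}.$$

Two conventions were genuinely open and are exposed as flags of
`prediction_interval()`:

* **Fixed-effect uncertainty.** $\mathrm{Var}(\hat\mu)$ can be added to the
  predictive variance (`include_fixed_uncertainty = TRUE`). At the normative
  cohort size of 76 subjects it changes the bounds in the fourth decimal, so
  it is off by default.
* **Normal vs Student-t quantile.** `use_t = TRUE` substitutes
  $t_{0.975,\,m-1}$. Again negligible at $m = 76$; off by default.

An age covariate can be entered as a centered fixed effect
(`covariates = "age"`, REML only), with the interval evaluated at the
covariate mean. It is off by default because the published normative
estimates are reproducible without it and the exact form of the original
correction is not recoverable.

## The synthetic normative cohort

No normative FA dataset is distributable, so `generate_measurements()`
emulates the study conditions: 76 subjects, 16 ROIs each (1216 observations),
partitioned as 6 basal-ganglia, 4 gray-matter, 2 freehand corpus-callosum and
4 circular corpus-callosum ROIs. The published tables report only the mean
and prediction interval per group, which fixes the *total* variance through
$\tau^2 + \sigma^2 = ((\mathrm{PI_{high}} - \mathrm{PI_{low}})/(2
z_{0.975}))^2$ but not its split; the generator assigns half of it between
subjects (`icc_fraction = 0.5`), a typical intraclass correlation for
repeated ROI measurements, configurable per group. The bilateral ROI
partition (putamen/pallidum/caudate; precentral gyrus/thalamus) is likewise a
package convention consistent with the published totals (16 ROIs, 14
circular) and is configurable.

Generated FA is clipped to [0, 1] after noise rather than resampled —
simpler, never drops records, and at the normative parameters the clipping
probability is below half a percent in the most extreme group, biasing means
by under 0.001.

What the generator does *not* emulate: measurement-placement variability of
a human rater, spatial correlation between neighboring ROIs, age trends, and
non-Gaussian tails. Passing parameter-recovery tests therefore shows the
estimator is correct and the pipeline is self-consistent under the stated
model, not that the model captures every feature of real cohorts.

The geometric phantom (`generate_phantom()`) is an analogous stand-in for
real FA volumes: nested regions (gray-matter shell at FA 0.25, deep
white-matter core at 0.70, paired "peduncle" spheres at 0.82, the normative
circular-ROI peduncle value) with Gaussian noise, and an `msa_delta`
parameter that depresses peduncle FA the way MSA does. Background voxels
stay exactly 0 rather than receiving clipped noise.

## LUT construction

`build_inflection_points()` places the anchors in FA order: half the
basal-ganglia PI lower bound, the BG lower bound and mean, the gray-matter
mean and upper bound, the freehand-callosum lower and upper bounds, and the
circular-callosum mean, bracketed by domain endpoints at 0 and 1. The halved
BG bound gives near-zero FA its own ramp instead of collapsing it onto the
endpoint color. With the published 12-MPG normative estimates the anchor
sequence is 0.0385, 0.077, 0.218, 0.323, 0.464, 0.627, 0.792, 0.858; a
non-monotone sequence (a pathological cohort) is an error naming the
offending pair, never silently reordered.

Colors ramp linearly per RGB channel between anchors, in continuous space,
and are rounded half-up to 8-bit integers only at the end
(interpolate-then-round). FA exactly at an anchor returns the anchor color
exactly; out-of-range FA is clamped to the endpoint colors, since excursions
beyond [0, 1] can only be numerical noise. Continuity holds at the rounding
scale (adjacent FA values differ by at most one level per channel), and on
the 256-entry export grid the default palette yields 256 distinct colors;
strict injectivity over the continuum is impossible after 8-bit rounding.

The published anchor colors are not recoverable in RGB (the printed figure is
CMYK), so the default palette is an explicit stand-in designed to the same
reading conventions — basal ganglia in dark blue/purple, gray matter in
green, dense white matter running red to yellow with rising FA so healthy
peduncles and callosum read as red/yellow — and ships as an editable YAML
config (`inst/extdata/palette_default.yaml`). Endpoint colors default to
black (FA 0) and white (FA 1).

Exports: the raw ImageJ `.lut` layout (exactly 768 bytes: 256 red, 256
green, 256 blue bytes on the closed uniform grid $k/255$) and a CSV
colormap (`index,fa,r,g,b`).

## Colorization and rendering

`colorize()` is a pure per-voxel map: finite in-mask voxels go through the
LUT, `NaN` and out-of-mask voxels get the background color (exact black by
default, deliberately independent of the `DOMAIN_MIN` color). No smoothing
or resampling is applied at any point — voxel values are rendered as
measured, and `render_mosaic()` uses nearest-voxel slicing only. Mosaics are
written as deterministic PNGs with a horizontal color-bar strip of the LUT,
radiological orientation by default.

## Validation statistics

`bland_altman()` implements the classical agreement analysis for paired
measurements of the same ROI under two acquisition schemes (12 vs 30
motion-probing-gradient directions): differences $d$, their mean, and the
95% prediction interval for a new difference as $\bar d \pm z_{0.975}
s_d$ with the $n-1$ sample SD, plus the Pearson correlation with a
two-sided p-value. A constant input side makes the correlation undefined;
it is returned as `NA` with a flag, never fabricated.

`screening_confusion()` scores MSA / non-MSA reads with MSA as the positive
class, keeping exact percentages internally and rounding half-up to whole
percent for reporting, the convention of printed rater tables.
`rater_summary()` averages the per-rater *printed* percentages (again
rounded half-up): with the published four-reader values (sensitivities 77,
100, 76, 65; specificities 70, 80, 86, 100) this gives 80% and 84%. Averaging
exact fractions instead would differ; the printed-precision convention is
used because per-rater raw call counts are not published, so only this
arithmetic is reproducible.

## Numerical choices and problem sizes

* $z_{0.975} = 1.959964$ is used both to invert PI half-widths into total
  SD in the generator and to form fitted PIs, keeping generation and
  estimation consistent.
* Constant within-group data short-circuit to $\hat\tau^2 = \hat\sigma^2 =
  0$ and a zero-width PI rather than entering the optimizer.
* Parameter-recovery experiments use 50 replicate cohorts of 76 subjects
  (the published cohort size); distributional properties of the generator
  are checked at 5000 subjects; prediction-interval coverage uses 200
  replicates with 60 held-out new-subject observations each. These sizes
  give Monte-Carlo standard errors an order of magnitude below the
  tolerances they are tested against.

## Known limitations

* The variance split (`icc_fraction`) is a convention, not an estimate; only
  the total variance is identified by the published intervals.
* Interpolation is in RGB, not a perceptually uniform space; palette
  optimization (e.g. colorblind safety) is out of scope.
* The human-rater screening study itself cannot be reproduced from published
  data; only its summary arithmetic is computed.
* Pediatric use would require age-specific normative scales; the model here
  targets the adult range.
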