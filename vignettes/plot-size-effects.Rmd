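---
title: "Plot-size effects in ALS-assisted biomass inventories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-size effects in ALS-assisted biomass inventories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsagb)
```

## Overview

`alsagb` studies how the size of circular field plots affects the quality of
area-based lidar biomass models and, through them, the precision of
model-assisted estimates of mean aboveground biomass (AGB). Because the
mechanism of interest — crowns spilling echoes across plot boundaries, and
positioning error misaligning field and lidar data — is geometric, it can be
reproduced faithfully in simulation. The package therefore couples a stand
and echo-cloud simulator to the full analysis chain: metric extraction,
model selection, cross-validation, boundary diagnostics, and design-based
estimation.

## The simulator and what it emulates

`generate_stand()` places stems by a homogeneous Poisson process (default
500 stems ha⁻¹ with dbh ≥ 5 cm, the usual tally threshold in tropical
inventory protocols). Diameters follow a Weibull distribution (shape 1.1,
scale 20 cm) left-truncated at 5 cm, which gives the reverse-J diameter
structure of natural tropical forest. Heights come from a saturating
diameter–height curve (`predict_height()`, asymptote ≈ 46.8 m) plus
Gaussian noise (default sd 0.5 m, a modest allowance for measurement and
allometric scatter), and per-tree biomass from the allometric power law
`AGB = 0.4020 dbh^1.4365 h^0.8613` (kg per tree; per-hectare scaling divides
by 1000). Crown radius is linear in diameter, `0.5 + 0.08 dbh` m capped at
12 m — wide enough that trees near a 200 m² plot boundary (radius 7.98 m)
routinely reach across it, which is the effect under study.

`simulate_point_cloud()` gives each tree a Poisson number of intercepted
pulses proportional to its crown disc area at the configured pulse density
(default 10.6 pulses m⁻²). Echo positions are uniform in the crown disc, so
clipping a plot later automatically includes echoes from trees rooted
outside it. First-return heights sit on a rounded-paraboloid crown envelope
`z = h (1 − (d/r)²)^γ` with γ = 0.5 plus the same Gaussian noise; half of
the canopy pulses additionally return a `last_of_many` echo drawn uniformly
between 0.3× and 1× the local envelope height. A configurable fraction of
pulses (default 0.20 — dense tropical canopies pass few pulses to the
ground) return ground-level echoes classified `single` or `last_of_many`.
Only the three classes used by the pooling convention are generated;
intermediate returns of multi-echo pulses are not simulated because the
analysis never consumes them.

Positioning error enters the pipeline the way it arises in the field: trees
are tallied around the *true* plot center while ALS metrics are extracted
around a center perturbed by an isotropic Gaussian displacement
(`perturb_plot_center()`, default sd 0.19 m per axis, the scale of
differential-GNSS planimetric error under canopy).

What the simulator deliberately does **not** reproduce: terrain and ground
classification (echoes arrive height-normalized), sensor trajectory and scan
geometry, crown overlap (trees intercept pulses independently), species
mixtures, and the spatial autocorrelation of real stands (plots are
independent draws; an optional density gradient along x can stand in for a
landscape biomass trend). Passing tests therefore demonstrate that the
*analysis chain* behaves correctly under the stated data-generating
assumptions, not that any specific field campaign's numbers are recovered.

## Metrics

For each plot, `single` + `first_of_many` echoes form the "first" dataset
and `single` + `last_of_many` the "last" dataset. A 2.0 m canopy threshold
removes ground and low-vegetation returns before the nine height percentiles
(`H10..H90`) and the summary statistics (`Hmax`, `Hmean`, `Hsd` with n−1
denominator, `Hcv`, moment skewness `g1 = m3/m2^{3/2}`) are computed.
Canopy densities `D0..D9` split the range between the lowest canopy height
(> 2 m) and the 95th percentile into ten equal fractions; `Di` is the
proportion of echoes *strictly above* threshold *i*, with the class's total
echo count (including sub-threshold echoes) as denominator, so `D0` reads as
canopy cover. Numerical conventions the data do not dictate were fixed once
for reproducibility: the linear-interpolation ("type 7") quantile
definition, strict inequality at density thresholds, and the population
moment coefficient for skewness. Plots with no canopy echoes yield missing
metrics and are excluded from modelling with a warning — never silently
zero-filled.

## Model selection and validation

Models regress log(AGB) on the metrics, offering each metric both raw and
log-transformed (log only where strictly positive). Selection is an
*exhaustive* enumeration of all subsets of one to three predictors,
implemented in compiled code over centered cross-products so the ~10⁵
candidate subsets per plot size cost milliseconds. Subsets with any variance
inflation factor ≥ 10 (diagonal of the inverse predictor correlation
submatrix) are discarded; the survivor minimizing
`BIC = n log(SSE/n) + (p + 1) log(n)` wins, with ties broken toward the
smaller subset and then lexicographic label order, so output is
deterministic. Coefficient significance is reported but never used as a
selection filter. An independent plain-R enumeration via `lm()` verifies the
compiled search in the test suite.

Back-transformation uses the half-MSE bias correction
(`exp(b0 + mse/2 + Σ bk xk)`), and the bias-corrected model feeds every
downstream consumer (boundary analysis and GREG residuals). Leave-one-out
cross-validation refits *coefficients* per fold while keeping the full-data
variable labels — re-selecting inside folds is available via
`loocv(refit_selection = TRUE)` but is not the default, because the quantity
of interest is the performance of the chosen model form, and per-fold
selection makes the per-size comparison noisier at n = 30. Accuracy is
summarized by RMSE% and MPE% with the `y − ŷ` sign convention (positive MPE%
= under-prediction).

## Boundary analysis

Relative residuals use the opposite convention, `(ŷ − y)/y`, chosen so that
a positive residual means the lidar "saw" more biomass than the field crew
tallied — exactly what buffer trees cause. Records are pooled across plot
sizes (200–1500 m² for 3 m buffers, 200–1100 m² for 6 m buffers; buffer
trees must have dbh > 10 cm) and modelled with a random intercept per plot
(`nlme::lme`), fixed effect either `SAGB_buffer` (total buffer AGB relative
to plot AGB) or `MAGB_buffer` (largest single buffer tree). Fitting is by
maximum likelihood, not REML, so AIC is comparable across the two
fixed-effect structures. Buffer biomass is expressed per hectare using the
*plot* area as reference, which keeps the ratios dimensionless and
comparable across plot sizes; the annulus area is available as an option. A
simple OLS of |relative residual| on plot size summarizes the overall size
trend; under boundary effects its slope is negative.

## Estimation

Per plot size, the field-based variance of the mean assumes simple random
sampling without finite-population correction; the model-assisted (GREG)
variance replaces observations with model residuals. Residuals default to
LOOCV predictions (honest out-of-sample errors); full-fit residuals are
available via `run_config(residual_source = "fullfit")` and are mildly
optimistic. Relative efficiency is the ratio of the two variances; the
algebraic identities (RE = 1 for a constant-at-mean predictor, V̂ = 0 for
perfect predictions) are asserted in the tests.

Plots differ in the maximum radius that could be measured in the field; the
default pool (31 m for 22 of 30 plots, 28, 26 and 25 m for the rest) means
sizes beyond ~1963 m² lose plots. Per-size analyses use the plots
measurable at that size; when sizes above 1900 m² are requested, a second,
consistent analysis restricted to the plots measurable at the largest radius
is reported alongside.

## Problem sizes and reproducibility

Default experiments use 30 plots and sizes 200–1900 m² in 100 m² steps; the
simulation-level checks in the test suite and the reproduction script
average 30 independent replicates, which keeps a full run in the
single-digit minutes on one core while leaving the replicate means stable.
All randomness flows from a single master seed: maximum radii and per-plot
sub-seeds are drawn first, then each plot's stand, cloud and center
perturbation use its own sub-stream, so results are reproducible and
insensitive to how many plot sizes are analysed.

## Known limitations

* The simulator's stands are spatially homogeneous within plots and
  independent between plots; real inventories face spatial autocorrelation
  and systematic designs whose SRS variance estimator is conservative.
* Crown interception ignores occlusion between neighbouring trees, so pulse
  densities inside dense canopies are slightly optimistic.
* The diameter–height and biomass allometries are treated as error-free
  beyond the configured height noise; allometric model error in real
  campaigns adds variance that the simulation does not represent.
* Absolute values of adjusted R², RMSE% and RE depend on the simulator's
  noise settings; the package's claims are directional (trends with plot
  size and RE > 1), which is what the tests assert.
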