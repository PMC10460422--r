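---
title: "Methods: projecting and decomposing PM2.5-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting and decomposing PM2.5-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25burden)
```

## The estimand

`pm25burden` estimates deaths attributable to ambient fine-particulate
(PM2.5) air pollution — hereafter the *attributable burden* — under joint
climate and socioeconomic scenarios, within the comparative risk assessment
framework. For a region and year, the burden is

$$
D \;=\; \sum_{a,d} \mathrm{PAF}_{a,d}\,\cdot\,\mathrm{POP}\cdot
\mathrm{Rate}_{a,d}\cdot \mathrm{AgeP}_a ,
$$

summed over fifteen five-year adult age bands $a$ (25–30 through 90–95,
plus an open >95 band; younger ages are excluded) and six causes of death
$d$ linked to PM2.5: chronic obstructive pulmonary disease, lower
respiratory infection, lung cancer, ischaemic heart disease, stroke, and
type 2 diabetes. $\mathrm{POP}$ is the total population,
$\mathrm{AgeP}_a$ the age-band proportion, $\mathrm{Rate}_{a,d}$ the
cause-specific death rate, and the population attributable fraction is

$$
\mathrm{PAF}_{a,d} = \frac{\mathrm{RR}_{a,d} - 1}{\mathrm{RR}_{a,d}},
$$

with the relative risk $\mathrm{RR}_{a,d}$ read from a tabulated
exposure–response curve at the region's population-weighted PM2.5
concentration. Curves are *consumed*, never fit: the meta-regression
ensembles that produce them (1000-draw curve fits) arrive as tables with a
mean curve and a draw matrix. We interpolate linearly between tabulated
nodes and extrapolate flat beyond the last node; both choices are
conventions of this package (the upstream tabulation does not dictate
either) and are deliberately conservative at high concentrations. Draw
values below RR = 1 are floored at 1 before the PAF transform (with the
count reported), since the pipeline estimates attributable deaths, not
benefits; no theoretical-minimum-risk counterfactual is subtracted — the
PAF is applied at the exposure level directly, which differs from some
burden-of-disease practice and is documented here for that reason.

## Exposure

Surface PM2.5 is composed from aerosol component fields,

$$
\mathrm{PM}_{2.5} = \mathrm{BC} + \mathrm{OA} + \mathrm{SO}_4 +
\mathrm{NH}_4 + 0.25\,\mathrm{SS} + 0.1\,\mathrm{dust},
\qquad \mathrm{NH}_4 = \tfrac{36}{96}\,\mathrm{SO}_4 ,
$$

where ammonium is imputed from sulfate on the assumption that it exists
only as ammonium sulfate (climate-model output typically omits surface
ammonium). The sea-salt and dust coefficients down-weight the coarse
fractions of those species. Dust is required as an input but defaults to
zero with a warning when absent.

Because modelled concentrations under-read observations, projected fields
are calibrated per grid cell against a baseline observation field:

$$
C^{\mathrm{cal}}_f = C^{\mathrm{obs}}_{bl}\cdot
\frac{C^{\mathrm{est}}_f}{C^{\mathrm{est}}_{bl}},
$$

with baseline quantities taken as multi-year means over a configurable
window (default 2015–2019; 2012–2019 is equally supported as the window is
an argument, not a constant). Calibration is per cell rather than per
region — a package choice, flagged as such. Cells with a zero baseline
estimate but positive observations are masked and counted rather than
crashing regional aggregates. The arithmetic is ordered as
$C^{\mathrm{obs}}\times(C_f/C_{bl})$ so the identity case
$C_f = C_{bl}$ returns the observation field bit-exactly.

Region-level exposure is the population-weighted mean
$\sum \mathrm{pop}\cdot C / \sum \mathrm{pop}$ over grid cells. Intensive
fields are regridded bilinearly; population counts conservatively by
area-overlap reallocation (global sums preserved whenever the target
covers the source). Multi-model spread is summarized, per region-year, as

$$
C_{CI} = \bar{C} \pm \sqrt{\mathrm{Var}(C)}\; t_{0.975}(n-1),
$$

i.e. a t interval on the ensemble *spread*, without the $1/\sqrt{n}$
standard-error factor a textbook interval on the mean would include. The
default mode implements this spread form; `ensemble_interval(mode =
"standard-error")` provides the textbook alternative. Both are exposed
because the two conventions answer different questions (where does a
model fall vs. where does the ensemble mean fall) and the package takes
no position beyond the reported default.

## Mortality forecasting

Cause-specific log death rates follow a hinged development model

$$
\ln m = \beta_1\,\min(\mathrm{SDI}, 0.8) +
\beta_2\,\max(\mathrm{SDI}-0.8, 0) + \theta_a\,t + \alpha_{l,a} +
\epsilon ,
$$

where SDI is the sociodemographic index in $[0,1]$, $t$ is the year index
from the first fitted year (calendar year would only shift the
intercepts), $\theta_a$ is a per-age-band time trend, and $\alpha_{l,a}$
are region-by-age intercepts. The two SDI slopes are *pooled* across
regions and ages ("global" coefficients); the hinge is a continuous
linear spline with one knot at SDI = 0.8 — continuity is imposed because
disjoint segments would make the fitted surface discontinuous in SDI,
which no development narrative supports. When all observed SDI sits on
one side of the knot the unidentifiable slope is pinned to the
identifiable one with a warning. Rates must be strictly positive; zero
rates are rejected rather than offset-adjusted (the synthetic generator
never produces them, and silent offsets distort elasticities).

In-sample residuals are modelled per stratum by an ARIMA process of
configurable order, default AR(1) — the minimal structure that captures
serial persistence in mortality shocks; non-convergent fits fall back to a
white-noise model with a warning. The point forecast is
$\exp(\hat{y} + \hat{\epsilon})$.

Prediction intervals are symmetric on the log scale:
$\hat{y} + \hat\epsilon \pm t_{0.975}(\nu)\sqrt{v}$. The default
prediction variance is the full-regression form
$v = s^2\,(1 + x_f'(X'X)^{-1}x_f)$ with $\nu$ the residual degrees of
freedom — this is the standard least-squares prediction variance, which
reduces to the familiar simple-regression expression
$s^2(1 + 1/n + (x_f-\bar x)^2/S_{xx})$ when a single covariate is fit.
An alternative `ci_mode = "as-printed"` evaluates the reduced expression
$s^2 \cdot (1/n) \cdot (x_f-\bar x)^2 / S_{xx}$ with $x$ = SDI and
$t(n-2)$, for comparison with reporting conventions that use it; it is
not a complete prediction variance (it omits the residual term) and is
not the default.

### Envelope constraining

Forecasting six causes independently does not respect all-cause
mortality. Forecasts are therefore passed through a two-round
cause-hierarchy constraint: level-2 causes (non-communicable diseases,
CMNND, injuries) are rescaled by a common factor per stratum so they sum
exactly to the forecast all-cause envelope; then each level-2 parent's
children — the named PM2.5-related causes plus an explicit "rest" cause —
are rescaled to the constrained parent. The factor is
$\mathrm{envelope}/\sum \mathrm{children}$, which is what makes the
constrained children sum to the envelope; the transposed factor
$\sum \mathrm{children}/\mathrm{envelope}$ (which moves rates *away* from
the envelope whenever children exceed it) is available behind
`orientation = "as-printed"` so both published readings of the scaling
can be reproduced. Constraining is applied within (region, year, age)
strata. Conservation is exact to floating-point at both levels, and is
tested as such.

## Interval propagation and reporting

Burden intervals follow simple bound combination: the lower bound
evaluates the product with the exposure-curve draws at their 2.5%
quantile, the concentration at its lower bound and the mortality rate at
its lower bound jointly, and analogously for the upper bound. This treats
the three sources as comonotone and is conservative; a Monte-Carlo mode
(`interval = "montecarlo"`) quantifies that conservatism by sampling the
inputs independently within their intervals. Reported series are smoothed
with a centered 5-year moving mean (shrinking at the series ends), applied
only at the reporting layer; driver decompositions use the smoothed
endpoint states, with raw annual endpoints available by passing
`window = 1`.

## Driver decomposition

The change in burden between two time points is attributed to four
drivers — age structure, total population, air quality, and disease
mortality — by stepwise introduction: walking an ordering of the four
factors, replacing each factor's start values with its end values across
all strata simultaneously, and recording the successive differences. Air
quality enters as the PAF table (the concentration→RR→PAF composition),
which keeps the product factorization exact. Contributions telescope
exactly to the net change within every ordering; the reported result
averages the 24 orderings, so the averaged contributions also sum exactly
to the net change. Per-factor contributions are path dependent across
consecutive periods — sub-period contributions need not add up to the
full-period attribution — and the tests demonstrate this rather than hide
it.

## The synthetic-data generators

The package ships no observational data; a first-class generator module
produces every input with known ground truth:

- **Aerosol fields**: spatially smooth, non-negative component fields
  built from Gaussian-blurred log-normal surfaces, with smooth
  multiplicative member perturbations (emulating multi-model spread) and
  compounded per-year concentration trends. The blur scale is a free
  parameter: the spatial covariance of real climate-model output is not
  prescribed anywhere, so only plausibility — smoothness and
  positivity — is targeted.
- **Population**: log-normal-like smooth weights, converted to integer
  counts by largest-remainder allocation so regional totals are conserved
  *exactly* (an intentionally testable contract).
- **Demography**: a gentle adult age pyramid tilted toward older bands at
  a scenario aging rate; proportions renormalized to sum to 1 within
  1e-12.
- **Mortality histories**: simulated directly from the hinged-SDI model
  above with AR(1) residuals; leaf causes are simulated, parent causes
  are exact sums of their children (the explicit "rest" causes guarantee
  a positive remainder), so hierarchy consistency holds by construction.
- **Exposure–response curves**: saturating concave curves
  $1 + a(1 - e^{-c/b})$ (log-linear and flat shapes available), with
  draw ensembles scattering the curvature multiplicatively so each draw
  is itself monotone with RR(0) = 1.

Default scenario settings encode four contrasting futures: concentration
trends compounding to roughly −47%, −29%, +8% and −37% over 2020–2035,
aging rates ordered so the rivalry-type scenario ages slowest, and
population growth of 0%, +3%, +6% and 0% respectively over the horizon.
These defaults are fixed study conditions, not tuning knobs.

What the generators do *not* emulate: real climatology or chemistry
(no seasonality, no secondary-aerosol formation), real geography (regions
are abstract labels), migration, cohort effects in mortality, or
correlation between exposure and demography. Passing tests therefore
demonstrate that the estimator machinery is correct and calibrated under
its own assumptions — not that those assumptions hold in any particular
country's data.

## Numerical choices and degenerate inputs

- Quantiles of draw ensembles use the linear-interpolation estimator
  (R type 7).
- Curve tables are floored at RR = 1 and monotonized with a running
  maximum at construction; both adjustment counts are retained.
- Zero-population regions, zero total deaths, and zero child-rate sums
  raise classed `undefined_value` conditions; argument violations raise
  `invalid_argument` — callers can distinguish them programmatically.
- Largest-remainder ties break by position (first cell wins),
  deterministically.
- All generators restore the caller's RNG state; identical seeds give
  bit-identical outputs, and the pipeline manifest records the seed so a
  run is reproducible end to end.

## Problem sizes used by the shipped checks

The package's own calibration checks run at deliberately modest sizes
chosen to exercise the asymptotics that matter while staying quick on one
CPU: coefficient recovery at 20 regions × 30 years × 5 age bands over 200
replicates (each coefficient within 3 standard errors of truth in ≥95% of
replicates); AR(1) residual recovery at series length 500; one-step
forecast-interval coverage over 500 replicates of a 20-year single-stratum
history with σ = 0.05 (empirical coverage required in [90%, 99%]);
decomposition exactness at 31 regions × 15 ages × 6 causes; envelope
conservation over 100 random hierarchy tables at 1e-12 relative
tolerance. The trend-recovery replicates use independent log-normal noise
(AR coefficient 0): ordinary-least-squares standard errors are only
correctly calibrated under independent errors, and the AR(1) component is
validated separately where its own standard errors apply.

## Known limitations

- All-cause demography is not reconciled with the population
  projections: the mortality envelope and the population inputs are
  internally consistent only through the synthetic generator, mirroring a
  known limitation of this class of pipeline.
- The bound-combination interval treats exposure, concentration and
  mortality uncertainty as comonotone; the Monte-Carlo mode shows this
  overstates interval width when the sources are independent.
- RR curves are flat beyond their last tabulated node, so burdens
  saturate at extreme concentrations.
- Gridded I/O uses long-format CSV with explicit (component, member,
  year, lat, lon) columns rather than a binary array format; the
  in-memory containers keep the array layout.
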