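---
title: "Bathythermal habitat modelling and climate-delta projection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bathythermal habitat modelling and climate-delta projection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bathytherm)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the design of the
synthetic-data generator, and the numerical conventions that matter when
checking results against an independent implementation.

## The occupancy model

Presence of a tagged animal in grid cell $i$ during month $t$ is modelled
as a Bernoulli outcome whose log-odds are quadratic in sea-surface
temperature and bottom depth:

$$\mathrm{logit}(p_{it}) = \beta_0 + \beta_1\,\mathrm{SST}_{it} +
\beta_2\,\mathrm{SST}_{it}^2 + \beta_3\,\mathrm{Depth}_{it} +
\beta_4\,\mathrm{Depth}_{it}^2 .$$

Concavity ($\beta_2,\beta_4<0$) encodes an ecological optimum: a species
with a preferred thermal envelope and a preferred depth band. The
maximising covariates are $-\beta_1/2\beta_2$ (°C) and $-\beta_3/2\beta_4$
(m), exposed by `fit_peaks()`.

`fit_logistic()` maximises the Bernoulli likelihood by Newton/IRLS with
step-halving. Covariates are standardised internally purely for numerical
conditioning — a quadratic in °C and m² spans five orders of magnitude —
and coefficients and their covariance are back-transformed, so everything
the user sees is in natural units. Convergence requires the score norm to
fall below $10^{-8}$ with a positive-definite information matrix; an
independent IRLS implementation then agrees with the returned coefficients
to better than $10^{-6}$ (this is asserted against `stats::glm`, which is
used in the test suite only as an oracle, never as the implementation).
Fits that fail the tolerance — e.g. under complete separation — are
returned flagged, with a warning.

Model selection is forward stepwise over
$\{\mathrm{SST},\mathrm{SST}^2,\mathrm{Depth},\mathrm{Depth}^2\}$ under the
quadratic hierarchy (a squared term may enter only after its linear term).
A candidate is added only when it both lowers AIC and raises the percent
deviance explained, $100\,(1-D_{res}/D_{null})$; the full trace is
returned. Diagnostics use randomised quantile residuals: for a Bernoulli
outcome a uniform draw from the CDF jump at the observed $y$, mapped
through $\Phi^{-1}$. These are standard normal when the model is correct.
A caution reflected in the tests: the *marginal*
distribution of these residuals stays uniform whenever the fitted
probabilities are calibrated within strata of the included covariates, so
misspecification must be diagnosed as residual *structure* against omitted
covariates (the suite uses a regression F-test of residuals on SST), not as
marginal non-normality.

### Pseudo-absences

The occurrence table contains one row per shelf cell per study month, with
$y=1$ where at least one tracked-animal daily position fell in the cell
that month and $y=0$ everywhere else. Absences are therefore *absences by
omission*: an unvisited cell-month may reflect true avoidance, limited
sample size, or tag deployment locations. This is the only construction
consistent with fitting a Bernoulli field over the whole grid, and it is
the main caveat when interpreting fitted probabilities as habitat
preference rather than as tagged-cohort space use.

## Track processing

Raw fixes are first cleaned with a speed filter (default 5 km/h, the
conventional cap for hard-shelled sea turtles): the fix whose removal most
reduces the number of violating consecutive pairs is deleted repeatedly
until no implied speed exceeds the bound, ties going to the later fix.
Speeds are great-circle distance over elapsed time on the raw lon/lat
coordinates, before any projection.

The movement model is a continuous-time correlated random walk: per axis,
velocity is an Ornstein-Uhlenbeck process with reversion rate $\beta$
(h⁻¹) and innovation magnitude $\sigma$ (m·h^(-3/2)), and position is its
integral. The stationary velocity standard deviation is
$\sigma/\sqrt{2\beta}$, so e.g. $\beta=0.2$, $\sigma=400$ gives ~0.6 km/h
typical speeds. Observations add isotropic Gaussian error $\tau$. The
likelihood is evaluated by a Kalman filter using the *exact* integrated-OU
transition over each irregular gap (no time discretisation), and verified
in the tests against a dense joint-Gaussian evaluation to $10^{-8}$.
Parameters are estimated by maximising over $(\log\beta, \log\sigma,
\log\tau)$ — Nelder-Mead followed by a BFGS polish with deterministic
jittered restarts — and daily 00:00 UTC positions come from the
Rauch-Tung-Striebel smoother, whose variance correctly grows inside
transmission gaps.

Conventions that an independent implementation must match to reproduce
likelihood values exactly: the state is initialised at the first fix with
position mean equal to the first observation, position variance $10^6$ m²
(1 km sd), and velocity drawn from its stationary distribution; both axes
share one covariance recursion. Daily interpolation is at 00:00 UTC — the
choice of time-of-day is a convention, not a result.

## Geometry

All geographic arithmetic lives on a sphere of radius 6 371 008.8 m. The
study projection is an oblique Mercator centred on 35°N, 75°W with an
east-west central line, built by rotating the sphere so the centre maps to
the rotated equator and applying the standard Mercator map. It is conformal
and length-true along the central line; over the shelf study area
round-trip error is far below 1 m and chord distances match great-circle
distances to well under 0.1%. The analysis grid is a uniform 10-km lattice
in this plane; positions are binned with half-open cell intervals
$[\text{edge}, \text{edge}+10\,\mathrm{km})$ so boundary points belong to
exactly one cell. Coarse SST products are regridded by unweighted averaging
of the pixels whose centres fall in a cell, with nearest-pixel fallback for
cells containing no pixel centre — this preserves constant fields exactly.

The study mask keeps water cells with depth < 200 m (strict) between
33.5°N and 41.6°N, the shelf band where the tagged cohort concentrated.

## Classification and projection

`roc_curve()` computes sensitivity and specificity by exact counting at
every unique score (prediction positive iff score ≥ threshold) and the AUC
by the trapezoidal rule, which equals the Mann-Whitney rank statistic with
ties counted half — asserted to $10^{-12}$ in the tests. The occupancy
cut-point minimises $IU(c)=|Se(c)-AUC|+|Sp(c)-AUC|$ by exhaustive scan
over the observed scores (the same candidate set the standard ROC tooling
uses); ties are broken by smaller $|Se-Sp|$, then by the smaller
threshold — the first tie-break follows the criterion's published
rationale, the second is arbitrary but deterministic.

Projection adds monthly climate-model SST deviations ("deltas") to the
observed monthly climatology — depth held constant — and re-predicts
probability for every cell × month × projection year, classifying at the
selected cut-point. Masked cells are *missing*, never absent. Seasonal
summaries average probabilities within Jan–Mar, Apr–Jun, Jul–Sep, Oct–Dec
and within 10- or 20-year bins; the occupied fraction classifies the
seasonal-mean probability field and counts the share of shelf cells
flagged (the alternative — classify monthly, then average indicators — is
available as `fraction_mode = "classify-then-mean"`). Bin 0 of every trend
table is the observed era, predicted from the climatology itself, so a
zero-delta projection reproduces bin 0 exactly — this identity is tested
bit-for-bit. Deltas are applied per projection year and summarised after
prediction; bin-averaging deltas before prediction would give slightly
different numbers for a nonlinear response and is deliberately not done.

Two covariate-space summaries are provided and kept distinct, because the
field uses both: the *presence envelope* (observed covariate ranges at
presences, `presence_envelope()`) and the *core habitat* (the region with
predicted $p \ge c$, `core_habitat_envelope()`). The "highest probability"
region reported by the acceptance script takes the top quartile of
predicted values within the classified habitat, which nests inside the
core envelope; the plain `top_quartile_habitat()` field operation uses the
75th percentile of all unmasked cell values (inclusive type-7 quantile —
stated because quantile definitions differ across software).

## The synthetic-data generator

The generator exists so that every downstream stage can be validated
against planted truth without proprietary tracking data. Its defaults are
the study conditions and were chosen once, on realism grounds, during
design:

* **Grid**: 10-km cells over 77–65°W, 33–42°N; a linear coastline running
  south-west to north-east (1.2° latitude per ° longitude through 35.5°N at
  75°W) so land occupies the north-west, as on the US Atlantic seaboard.
* **Bathymetry**: depth ramps offshore at 4 m/km, saturating at 320 m,
  with the slope divided by a factor growing to 3.5 at the northern edge
  (`widen_north = 2.5`). This makes the southern shelf narrow (~50 km) and
  the northern shelf broad (~175 km), the defining contrast between the
  Middle Atlantic Bight and the Southern New England/Georges Bank shelf,
  and it concentrates shelf area in cool northern water — the geometry
  that drives the seasonal projection fingerprint.
* **SST climatology**: annual mean 15 °C at 37.5°N falling 1.2 °C per
  degree of latitude northward (≈20 °C off Hatteras, ≈10 °C at the Gulf of
  Maine edge), seasonal half-range 8.5 °C peaking in September — shelf SST
  lags the insolation maximum — giving winters of ~3–13 °C and summers of
  ~17–27 °C across the band.
* **Warming deltas**: linear ramp to a spatial mean of +3 °C at year 80,
  multiplied by a north-south gradient (+50% of the spread at the northern
  edge) and normalised so the year-80 spatial mean is exactly the
  configured warming; months share the annual delta.
* **Truth surface**: parameterised by its ecology — peak at 21.5 °C and
  50 m, peak probability 0.5, and probability 0.08 at 21.5 ± 6.5 °C and
  50 ± 42 m — matching the published peak and core-range structure for
  Northwest Atlantic loggerheads.
* **Tracks**: exact integrated-OU simulation over the observation
  schedule, isotropic Gaussian fix error (default 1.5 km), and errant
  fixes planted by displacing a configurable fraction of fixes 150 km in a
  random direction — far enough to violate the 5 km/h bound against any
  neighbour at the default 3-h transmission interval. True states are
  retained for verification.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: Argos location-class error structure, behavioural
mode switching, tag transmission dropout correlated with behaviour,
spatially correlated SST anomalies, interannual variability, and effort
bias in deployments. The planted-truth draws are independent Bernoulli
outcomes, so residual autocorrelation — present in real tracking data even
after daily interpolation, and not corrected by the model — does not arise
in simulation; with real data the reported standard errors would be
anti-conservative.

With these defaults the end-to-end study behaves like the system it
emulates: warming expands occupancy most in spring and fall (below-peak
transitional water over the broad northern shelf moves into the envelope),
contracts it slightly in summer (the warm southern edge overshoots the
optimum), and leaves winter nearly unchanged (winter water stays below the
envelope nearly everywhere). The acceptance suite asserts exactly this
qualitative fingerprint, plus recovery of the planted optimum within
0.5 °C and 5 m.

## Numerical choices and degenerate inputs

* Logistic fit: score-norm tolerance $10^{-8}$ (standardised scale),
  step-halving guarantees a non-decreasing likelihood, AIC identity
  $-2\ell + 2k$ holds exactly for every fit.
* CTCRW: parameters optimised on the log scale; standard errors by the
  delta method from the numerically evaluated Hessian; `diffusion = 0` is
  a valid degenerate input (the animal never moves), `reversion` must be
  positive.
* Speed filter: a track whose violations cannot be resolved without
  removing essentially everything fails loudly rather than returning a
  single fix.
* Classification: probabilities exactly equal to the cut-point are
  occupied (≥ rule); constant fields flag every cell in
  `top_quartile_habitat()` with a warning; empty masks, single-class
  labels, degenerate grid extents and misaligned fields all fail with
  explicit errors rather than propagating nonsense.
* Problem sizes: the default study uses ~11,600 cells (674 shelf),
  80,880 occurrence rows and a 960-field projection and runs in ~10 s; the
  test suite simulates 50 replicate fits at n = 50,000 for GLM calibration
  and 50 CTCRW tracks of 150 fixes for coverage, sizes at which binomial
  tolerance bands on the asserted rates are tight enough to be meaningful.

## Known limitations

* No spatial or temporal autocorrelation correction in the GLM; daily
  interpolation is the only mitigation, as in the analysis this package
  reimplements.
* A single shared observation-error parameter across tags; per-tag-type
  errors are an extension point in the data model.
* The occupied-fraction trend conflates habitat suitability with the
  tagged cohort's space use (see the pseudo-absence caveat).
* The climate scenario is a stylised delta ramp, not climate-model output;
  it is meant to exercise the projection machinery, not to forecast.
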