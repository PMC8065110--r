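# bathytherm

Tools for characterizing the **bathythermal habitat** of satellite-tagged
marine megafauna and projecting how that habitat shifts as the ocean warms.
The package implements, end to end, the analysis pipeline used for loggerhead
sea turtles on the Northwest Atlantic continental shelf: telemetry cleaning
and state-space smoothing, gridded presence/absence construction, a quadratic
logistic species distribution model on sea-surface temperature (SST) and
depth, ROC-based occupancy classification, and climate-delta projection.
Because multi-year tracking data are rarely public, a first-class
synthetic-data module generates every input — environment grids, SST
climatologies, warming deltas, noisy tracks, and occupancy draws from a known
logistic surface — so each stage is testable against planted truth.

Intended users: movement ecologists and fisheries/protected-species
scientists building presence-only SDMs from telemetry, and anyone who needs
a transparent, testable reference implementation of this class of pipeline.

## The model

Occupancy of grid cell *i* in month *t* is Bernoulli,

```
y_it ~ Bernoulli(p_it)
logit(p_it) = b0 + b1 SST_it + b2 SST_it^2 + b3 Depth_it + b4 Depth_it^2
```

with concave quadratic responses (`b2, b4 < 0`), so the fitted surface has a
thermal/bathymetric optimum at `(-b1/2b2, -b3/2b4)`. Terms are chosen by
forward stepwise selection (a term enters only if it lowers AIC *and* raises
the percent deviance explained). Fitted probabilities are converted to
occupancy with the cut-point `c` minimizing the Index of Union

```
IU(c) = |Se(c) - AUC| + |Sp(c) - AUC|
```

over the ROC curve. Projection uses the climate-delta method: monthly SST
anomalies are added to the observed monthly climatology (depth held
constant), probabilities are re-predicted for 80 years, classified at `c`,
and summarized as the occupied fraction of shelf cells by season and decade.

Upstream, raw tracks are cleaned with a 5 km/h speed filter and smoothed
with a continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
velocity model) fitted by Kalman-filter maximum likelihood; daily positions
come from the Rauch-Tung-Striebel smoother and are aggregated onto a 10-km
oblique-Mercator grid.

## Worked example

Run the full synthetic study: ten years of occupancy draws from a planted
surface peaking at 21.5 °C / 50 m on a 10-km shelf grid (33.5–41.6 °N,
depths < 200 m), then an 80-year projection with ~3 °C north-graded warming.

```r
library(bathytherm)
res <- run_pipeline(pipeline_config(seed = 1))

res$fit
#> <habitat_fit> n = 80880, logLik = -8351.49, AIC = 16712.98, %dev = 44.37
#> (Intercept)         sst        sst2       depth      depth2
#>  -30.364106    2.486409   -0.057683    0.141865   -0.001418

fit_peaks(res$fit)
#> $peak_sst   21.55234
#> $peak_depth 50.03228

res$cutpoint
#> <cutpoint> c = 0.0479 (IU = 0.1037, Se = 0.949, Sp = 0.845, AUC = 0.949)

core_habitat_envelope(res$fit, res$cutpoint$c)[c("sst", "depth")]
#> $sst   14.4 28.7      # degC with predicted p >= c
#> $depth  4.5 95.5      # m

res$trend[res$trend$bin == 8, ]
#>   season bin occupied_fraction change_vs_observed
#> 1 winter   8            0.0312             0.0312
#> 2 spring   8            0.1780             0.1039
#> 3 summer   8            0.4006            -0.0193
#> 4   fall   8            0.4125             0.0341
```

The fitted optimum recovers the planted truth (21.5 °C / 50 m) to within a
few hundredths, the core-habitat envelope brackets the planted envelope
(15–28 °C / 8–92 m), and the final-decade trend shows the expected seasonal
fingerprint of shelf warming: the largest habitat gains in spring and fall,
a slight summer decline as the warm southern edge overshoots the optimum,
and minimal winter change because winter water stays below the envelope.

A command-line wrapper with the same defaults lives at
`inst/scripts/bathytherm-pipeline.R`
(`Rscript inst/scripts/bathytherm-pipeline.R --seed 1 --out pipeline-out`).

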