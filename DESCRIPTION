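Package: bathytherm
Title: Bathythermal Habitat Modelling and Climate-Delta Projection for
    Satellite-Tagged Marine Megafauna
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for characterizing the bathythermal
    habitat of satellite-tagged marine animals and projecting occupancy
    under ocean warming. Cleans telemetry tracks with a speed filter, fits
    a continuous-time correlated random walk by Kalman-filter maximum
    likelihood and interpolates daily positions, aggregates positions onto
    a 10-km projected grid, fits a Bernoulli generalized linear model with
    quadratic sea-surface-temperature and depth terms, selects an occupancy
    cut-point by minimizing the Index-of-Union criterion on the ROC curve,
    and projects occupancy over multi-decade horizons by adding climate-model
    SST deltas to an observed monthly climatology. A synthetic-data module
    generates gridded environments, climatologies, warming deltas, noisy
    tracks, and occupancy draws from a known logistic surface so every stage
    is testable without proprietary tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
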