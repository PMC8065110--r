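proj_fixture <- function(horizon = 20, end_warming = 3, gradient = 0.5) {
  # all-ocean ramp: depths 0-180 m, so the whole depth envelope is populated
  g <- toy_grid(nx_km = 120, ny_km = 120, rate = 1.5)
  cl <- make_sst_climatology(g)
  d <- make_deltas(g, horizon_years = horizon, end_warming = end_warming,
                   north_south_gradient = gradient)
  tab <- simulate_occupancy(default_truth_surface(), g, cl, n_years = 4,
                            seed = 7)
  fit <- fit_logistic(tab)
  list(grid = g, clim = cl, deltas = d, fit = fit)
}

test_that("delta application is exact elementwise addition", {
  fx <- proj_fixture()
  z <- fx$deltas; z[] <- 0
  expect_equal(apply_deltas(fx$clim, z, 5, 7), unname(fx$clim[, 7]))
  u <- fx$deltas; u[] <- 3
  expect_equal(apply_deltas(fx$clim, u, 5, 7), unname(fx$clim[, 7]) + 3)
  expect_error(apply_deltas(fx$clim[1:5, ], fx$deltas, 1, 1), "aligned")
  expect_error(apply_deltas(fx$clim, fx$deltas, 99, 1), "horizon")
})

test_that("summing a regridded delta mesh equals summing pre-aligned fields", {
  g <- toy_grid(nx_km = 30, ny_km = 20)
  cl <- make_sst_climatology(g)
  # a coarse 0.1-degree-style mesh holding a linear-in-latitude delta field,
  # one pixel per cell, so regridding is exact pass-through
  ctr <- unproject_coordinates(g$x_center, g$y_center)
  mesh <- do.call(rbind, lapply(1:12, function(m)
    tibble::tibble(lon = ctr$lon, lat = ctr$lat, month = m,
                   sst = 2 + 0.5 * (ctr$lat - 36))))
  regridded <- monthly_sst(mesh, g)
  aligned <- 2 + 0.5 * (g$lat_center - 36)
  expect_equal(unname(regridded[, 6]), aligned, tolerance = 1e-9)
  expect_equal(cl[, 6] + regridded[, 6], cl[, 6] + aligned, tolerance = 1e-9)
})

test_that("zero-delta projection reproduces fitted-era probabilities exactly", {
  fx <- proj_fixture()
  z <- fx$deltas; z[] <- 0
  pr <- project_occupancy(fx$fit, fx$clim, z, fx$grid, c = 0.08)
  shelf <- fx$grid$shelf_mask
  for (m in c(2, 8)) {
    direct <- predict_probability(fx$fit, fx$clim[shelf, m],
                                  fx$grid$depth[shelf])
    expect_identical(pr$probability[shelf, m, 1], unname(direct))
    expect_identical(pr$probability[shelf, m, 20], unname(direct))
  }
  # masked cells are missing, never absent
  expect_true(all(is.na(pr$probability[!shelf, , ])))
  expect_true(all(is.na(pr$occupancy[!shelf, , ])))
  expect_true(all(pr$occupancy[shelf, , ] %in% 0:1))
  # counting: 12 * horizon monthly fields
  expect_equal(dim(pr$probability), c(nrow(fx$grid), 12, 20))
})

test_that("uniform warming shifts probability by the quadratic response sign", {
  fx <- proj_fixture(horizon = 10, end_warming = 2, gradient = 0)
  pr <- project_occupancy(fx$fit, fx$clim, fx$deltas, fx$grid, c = 0.08)
  shelf <- which(fx$grid$shelf_mask)
  pk <- fit_peaks(fx$fit)
  # June water sits below the fitted peak, September water above it
  for (m in c(6, 9)) {
    sst0 <- fx$clim[shelf, m]
    p0 <- pr$probability[shelf, m, 1]   # year 1: +0.2 degC
    p9 <- pr$probability[shelf, m, 10]  # year 10: +2 degC
    below <- sst0 < pk$peak_sst - 2.5   # stays below the peak after warming
    above <- sst0 > pk$peak_sst
    expect_gt(sum(below) + sum(above), 100)
    expect_true(all(p9[below] > p0[below]))
    expect_true(all(p9[above] < p0[above]))
  }
})

test_that("seasonal summaries count occupied fractions correctly", {
  fx <- proj_fixture(horizon = 20)
  pr <- project_occupancy(fx$fit, fx$clim, fx$deltas, fx$grid, c = 0.08)
  sm <- seasonal_decadal_summary(pr, fx$fit, fx$clim, fx$grid, bin_width = 10)
  expect_setequal(unique(sm$table$season),
                  c("winter", "spring", "summer", "fall"))
  expect_equal(sort(unique(sm$table$bin)), 0:2)
  expect_true(all(sm$table$occupied_fraction >= 0 &
                  sm$table$occupied_fraction <= 1))
  # occupied fraction is monotone non-increasing in the cut-point
  f <- sm$fields[["summer.2"]]
  shelf <- fx$grid$shelf_mask
  fr <- vapply(c(0, 0.05, 0.2, 0.6, 1),
               function(cc) mean(classify_occupancy(f, cc)[shelf]), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[1], 1)  # c = 0: every shelf cell occupied
  # a field sitting exactly at the cut-point counts as occupied
  f2 <- ifelse(shelf, 0.08, NA)
  expect_equal(mean(classify_occupancy(f2, 0.08)[shelf]), 1)
  # exact fraction: 25 of the first 100 shelf cells above c
  idx <- which(shelf)[1:100]
  f3 <- rep(NA_real_, length(shelf)); f3[shelf] <- 0
  f3[idx[1:25]] <- 0.5
  expect_equal(mean(classify_occupancy(f3, 0.1)[shelf] == 1) *
                 sum(shelf) / 100, 0.25)
  expect_error(seasonal_decadal_summary(pr, fx$fit, fx$clim, fx$grid,
                                        bin_width = 50), "bin")
})

test_that("trend report round-trips fractions and baselines changes at bin 0", {
  fx <- proj_fixture(horizon = 20)
  pr <- project_occupancy(fx$fit, fx$clim, fx$deltas, fx$grid, c = 0.08)
  sm <- seasonal_decadal_summary(pr, fx$fit, fx$clim, fx$grid, bin_width = 10)
  tr <- habitat_trend_report(sm)
  expect_equal(nrow(tr), 4 * 3)
  merged <- merge(tr, sm$table, by = c("season", "bin"))
  expect_equal(merged$occupied_fraction.x, merged$occupied_fraction.y)
  expect_true(all(tr$change_vs_observed[tr$bin == 0] == 0))
  # zero-delta projection: every change is zero
  z <- fx$deltas; z[] <- 0
  pr0 <- project_occupancy(fx$fit, fx$clim, z, fx$grid, c = 0.08)
  sm0 <- seasonal_decadal_summary(pr0, fx$fit, fx$clim, fx$grid, bin_width = 10)
  tr0 <- habitat_trend_report(sm0)
  expect_true(all(tr0$change_vs_observed == 0))
})
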