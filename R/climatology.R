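#' Synthetic monthly SST climatology
#'
#' Builds a per-cell, per-calendar-month mean sea-surface temperature field:
#' a latitudinal ramp plus a sinusoidal seasonal cycle plus optional noise.
#' The defaults emulate the Northwest Atlantic shelf from Cape Hatteras to
#' the Gulf of Maine: ~15 degC annual mean at 37.5N (about 20 degC in the
#' south of the band, 10 degC in the north), cooling 1.2 degC per degree of
#' latitude northward, and a +/- 8.5 degC seasonal swing peaking in
#' September (sea surface temperature lags the insolation maximum by about
#' a month over the shelf).
#'
#' @param grid an `env_grid`.
#' @param mean_at_ref annual-mean SST (degC) at `ref_lat`.
#' @param ref_lat reference latitude (degrees).
#' @param lat_gradient degC change per degree of latitude increase
#'   (negative = cooler northward).
#' @param seasonal_amplitude half-range of the seasonal cycle (degC, >= 0).
#' @param peak_month calendar month (1-12) at which the cycle peaks.
#' @param noise_sd sd of cellwise monthly noise (degC).
#' @param seed integer seed for the noise.
#' @return an `sst_clim`: a numeric matrix (cells x 12, degC), NA on land.
#' @export
make_sst_climatology <- function(grid, mean_at_ref = 15, ref_lat = 37.5,
                                 lat_gradient = -1.2,
                                 seasonal_amplitude = 8.5, peak_month = 9,
                                 noise_sd = 0, seed = NULL) {
  assert_that(inherits(grid, "env_grid"), "grid must be an env_grid")
  assert_that(seasonal_amplitude >= 0, "seasonal_amplitude must be >= 0")
  base <- mean_at_ref + lat_gradient * (grid$lat_center - ref_lat)
  season <- seasonal_amplitude * cos(2 * pi * ((1:12) - peak_month) / 12)
  sst <- outer(base, rep(1, 12)) + outer(rep(1, nrow(grid)), season)
  if (noise_sd > 0)
    sst <- with_seed(seed, sst + matrix(stats::rnorm(length(sst), 0, noise_sd),
                                        nrow(sst)))
  sst[grid$land_mask, ] <- NA_real_
  colnames(sst) <- month.abb
  structure(sst, class = c("sst_clim", "matrix", "array"))
}

#' Synthetic climate-model SST deltas
#'
#' Generates per-cell, per-month, per-projection-year SST deviations from
#' the observed climatology, emulating monthly anomalies from a
#' high-resolution climate model. Warming ramps linearly from 0 to
#' `end_warming` over the horizon, optionally graded with latitude so that
#' the northern part of the domain warms faster (as projected for the Gulf
#' of Maine); the grading is normalised so the spatial mean at the final
#' year equals `end_warming` exactly.
#'
#' @param grid an `env_grid`.
#' @param horizon_years projection horizon H (years, >= 1).
#' @param end_warming spatial-mean warming at year H (degC); the default 3
#'   matches the projected ~3 degC shelf-wide increase over 60-80 years.
#' @param north_south_gradient relative extra warming across the latitude
#'   range (0 = uniform; 0.5 = the northern edge warms ~50% of the spread
#'   more than the southern edge).
#' @return a `delta_series`: numeric array (cells x 12 months x H years).
#' @export
make_deltas <- function(grid, horizon_years = 80, end_warming = 3,
                        north_south_gradient = 0.5) {
  assert_that(inherits(grid, "env_grid"), "grid must be an env_grid")
  assert_that(horizon_years >= 1, "horizon_years must be >= 1")
  lat <- grid$lat_center
  w <- if (diff(range(lat)) > 0 && north_south_gradient != 0) {
    v <- 1 + north_south_gradient * (lat - mean(range(lat))) / diff(range(lat))
    v / mean(v)
  } else rep(1, length(lat))
  ramp <- end_warming * seq_len(horizon_years) / horizon_years
  d <- outer(w, rep(1, 12)) %o% ramp  # cells x 12 x H
  structure(d, class = c("delta_series", "array"))
}
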