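#' Known logistic truth surface for simulation
#'
#' A quadratic logistic presence surface
#' `logit(p) = b0 + b1*SST + b2*SST^2 + b3*Depth + b4*Depth^2`
#' used as the generative truth for occupancy draws. `truth_surface()`
#' takes raw coefficients; `truth_from_peaks()` parameterises the same
#' surface by its scientifically interpretable features: the peak location,
#' the peak probability, and the half-widths at which probability falls to
#' `edge_prob`.
#'
#' @param beta numeric length-5 vector `(b0, b1, b2, b3, b4)`.
#' @return a `truth_surface` with elements `beta`, `peak_sst`, `peak_depth`.
#' @export
truth_surface <- function(beta) {
  assert_that(length(beta) == 5 && all(is.finite(beta)),
              "beta must be 5 finite coefficients")
  beta <- stats::setNames(as.numeric(beta),
                          c("(Intercept)", "sst", "sst2", "depth", "depth2"))
  if (beta[["sst2"]] >= 0 || beta[["depth2"]] >= 0) {
    warning("truth surface is not concave in SST and depth; peaks undefined")
    pk_s <- pk_d <- NA_real_
  } else {
    pk_s <- -beta[["sst"]] / (2 * beta[["sst2"]])
    pk_d <- -beta[["depth"]] / (2 * beta[["depth2"]])
  }
  structure(list(beta = beta, peak_sst = pk_s, peak_depth = pk_d),
            class = "truth_surface")
}

#' @rdname truth_surface
#' @param peak_sst,peak_depth covariate values (degC, m) at maximum
#'   probability.
#' @param peak_prob probability at the peak.
#' @param edge_prob probability at the envelope edges.
#' @param sst_halfwidth,depth_halfwidth distance from the peak (degC, m) at
#'   which probability drops to `edge_prob` with the other covariate held at
#'   its peak.
#' @export
truth_from_peaks <- function(peak_sst = 21.5, peak_depth = 50,
                             peak_prob = 0.5, edge_prob = 0.08,
                             sst_halfwidth = 6.5, depth_halfwidth = 42) {
  assert_that(peak_prob > edge_prob && edge_prob > 0 && peak_prob < 1,
              "need 0 < edge_prob < peak_prob < 1")
  a <- stats::qlogis(peak_prob)
  drop <- stats::qlogis(edge_prob) - a  # negative
  b2 <- drop / sst_halfwidth^2
  b4 <- drop / depth_halfwidth^2
  truth_surface(c(a + b2 * peak_sst^2 + b4 * peak_depth^2,
                  -2 * b2 * peak_sst, b2, -2 * b4 * peak_depth, b4))
}

#' @rdname truth_surface
#' @export
default_truth_surface <- function() truth_from_peaks()

#' @export
print.truth_surface <- function(x, ...) {
  cat("<truth_surface> peak", round(x$peak_sst, 2), "degC /",
      round(x$peak_depth, 1), "m\n")
  print(x$beta)
  invisible(x)
}

truth_probability <- function(truth, sst, depth) {
  b <- truth$beta
  stats::plogis(b[1] + b[2] * sst + b[3] * sst^2 + b[4] * depth + b[5] * depth^2)
}

#' Direct Bernoulli occupancy draws from a known surface
#'
#' For every shelf cell and study month, draws presence/absence from the
#' truth surface evaluated at the climatological SST and the cell depth.
#' This is the planted-truth input used to validate the model-fitting
#' stages without tracking data.
#'
#' @param truth a [truth_surface()].
#' @param grid an `env_grid` with the shelf mask applied.
#' @param climatology an `sst_clim` for the same grid.
#' @param months calendar months to simulate (subset of 1:12).
#' @param n_years number of independent annual replicates of those months
#'   (emulating a multi-year study period).
#' @param seed integer seed.
#' @return an `occurrence_table`: tibble with columns `cell_id`, `year`,
#'   `month`, `y`, `sst_c`, `depth_m`; the truth is kept in
#'   `attr(, "truth")`.
#' @export
simulate_occupancy <- function(truth, grid, climatology, months = 1:12,
                               n_years = 1, seed = NULL) {
  assert_that(inherits(truth, "truth_surface"), "truth must be a truth_surface")
  assert_that(!all(is.na(grid$shelf_mask)) && any(grid$shelf_mask),
              "grid has no shelf cells; run apply_study_mask() first")
  shelf <- which(grid$shelf_mask)
  base <- expand.grid(cell = shelf, month = as.integer(months))
  sst1 <- climatology[cbind(base$cell, base$month)]
  dep1 <- grid$depth[base$cell]
  p1 <- truth_probability(truth, sst1, dep1)
  tab <- tibble::tibble(
    cell_id = rep(grid$cell_id[base$cell], n_years),
    year = rep(seq_len(n_years), each = nrow(base)),
    month = rep(base$month, n_years),
    sst_c = rep(sst1, n_years),
    depth_m = rep(dep1, n_years))
  tab$y <- with_seed(seed, stats::rbinom(nrow(tab), 1L, rep(p1, n_years)))
  tab <- tab[, c("cell_id", "year", "month", "y", "sst_c", "depth_m")]
  structure(tab, class = c("occurrence_table", class(tab)), truth = truth)
}

#' Simulate satellite-telemetry tracks from a CTCRW
#'
#' Generates animal tracks from the exact integrated Ornstein-Uhlenbeck
#' (continuous-time correlated random walk) transition over an irregular
#' observation schedule, adds isotropic Gaussian observation noise, and
#' plants a configurable fraction of errant fixes displaced far enough to
#' violate a 5 km/h speed bound against their neighbours. True states are
#' retained for testing.
#'
#' @param n_animals number of tracks.
#' @param ctcrw_params list with `reversion` (1/h), `diffusion`
#'   (m h^-3/2): the OU velocity has stationary standard deviation
#'   `diffusion / sqrt(2 * reversion)` m/h per axis.
#' @param obs_schedule numeric vector of observation times in hours from
#'   deployment (strictly increasing), or a list of one such vector per
#'   animal.
#' @param noise_sd observation-error sd (m) per axis.
#' @param errant_rate expected fraction of fixes displaced as errant.
#' @param errant_displacement displacement distance (m) of errant fixes.
#' @param start_lonlat deployment location, `c(lon, lat)`, recycled.
#' @param start_time POSIXct deployment instant (UTC).
#' @param center,azimuth projection used to express tracks in lon/lat.
#' @param seed integer seed.
#' @return a list of `raw_track` tibbles (columns `animal_id`, `time`,
#'   `lon`, `lat`) with attributes `truth` (true states: `time_h`, `x`,
#'   `y`, `vx`, `vy`), `errant` (logical) and `params`.
#' @export
simulate_tracks <- function(n_animals = 1,
                            ctcrw_params = list(reversion = 0.2, diffusion = 400),
                            obs_schedule = seq(0, 720, by = 3),
                            noise_sd = 1500, errant_rate = 0,
                            errant_displacement = 150000,
                            start_lonlat = c(-74, 36),
                            start_time = as.POSIXct("2014-06-01", tz = "UTC"),
                            center = c(-75, 35), azimuth = 90, seed = NULL) {
  b <- ctcrw_params$reversion; s <- ctcrw_params$diffusion
  assert_that(is.numeric(b) && b > 0, "reversion must be > 0")
  assert_that(is.numeric(s) && s >= 0, "diffusion must be >= 0")
  assert_that(noise_sd >= 0 && errant_rate >= 0 && errant_rate <= 1,
              "invalid noise_sd or errant_rate")
  sched <- if (is.list(obs_schedule)) obs_schedule else
    rep(list(obs_schedule), n_animals)
  assert_that(length(sched) == n_animals,
              "obs_schedule list must have one entry per animal")
  for (tv in sched)
    if (any(diff(tv) <= 0)) stop_bt("observation times must be strictly increasing")
  start_xy <- project_coordinates(start_lonlat[1], start_lonlat[2],
                                  center = center, azimuth = azimuth)
  with_seed(seed, lapply(seq_len(n_animals), function(a) {
    tv <- sched[[a]]
    n <- length(tv)
    st <- matrix(0, n, 4, dimnames = list(NULL, c("x", "y", "vx", "vy")))
    st[1, c("x", "y")] <- c(start_xy$x, start_xy$y)
    if (s > 0) st[1, c("vx", "vy")] <- stats::rnorm(2, 0, s / sqrt(2 * b))
    if (n > 1) for (k in 2:n) {
      dt <- tv[k] - tv[k - 1]
      e <- exp(-b * dt)
      qv <- s^2 * (1 - e^2) / (2 * b)
      qxv <- s^2 * (1 - e)^2 / (2 * b^2)
      qx <- s^2 / b^2 * (dt - 2 * (1 - e) / b + (1 - e^2) / (2 * b))
      # joint draw of (position, velocity) increment per axis
      L11 <- sqrt(qx)
      L21 <- if (qx > 0) qxv / L11 else 0
      L22 <- sqrt(max(0, qv - L21^2))
      for (ax in 1:2) {
        z <- stats::rnorm(2)
        st[k, ax] <- st[k - 1, ax] + st[k - 1, ax + 2] * (1 - e) / b + L11 * z[1]
        st[k, ax + 2] <- st[k - 1, ax + 2] * e + L21 * z[1] + L22 * z[2]
      }
    }
    ox <- st[, "x"] + stats::rnorm(n, 0, noise_sd)
    oy <- st[, "y"] + stats::rnorm(n, 0, noise_sd)
    errant <- stats::runif(n) < errant_rate
    if (any(errant)) {
      th <- stats::runif(sum(errant), 0, 2 * pi)
      ox[errant] <- ox[errant] + errant_displacement * cos(th)
      oy[errant] <- oy[errant] + errant_displacement * sin(th)
    }
    ll <- unproject_coordinates(ox, oy, center = center, azimuth = azimuth)
    trk <- tibble::tibble(animal_id = sprintf("sim%03d", a),
                          time = start_time + tv * 3600,
                          lon = ll$lon, lat = ll$lat)
    structure(trk, class = c("raw_track", class(trk)),
              truth = tibble::tibble(time_h = tv, x = st[, "x"], y = st[, "y"],
                                     vx = st[, "vx"], vy = st[, "vy"]),
              errant = errant, params = ctcrw_params, noise_sd = noise_sd)
  }))
}
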