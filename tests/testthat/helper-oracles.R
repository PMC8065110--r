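# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the CTCRW oracle builds the dense joint
# Gaussian covariance directly, the AUC oracle uses the rank statistic, the
# speed-filter oracle enumerates subsets.

EARTH_R <- 6371008.8

# Dense multivariate-normal CTCRW log-likelihood: builds the full joint
# covariance of all observed positions from the integrated-OU transition
# and evaluates the Gaussian density directly (per axis, mean anchored at
# the first fix as in the package's stated initial condition).
dense_ctcrw_loglik <- function(xy, pars, p0x = 1e6) {
  b <- pars$reversion; s <- pars$diffusion; tau <- pars$obs_error_sd
  h <- xy$hours; n <- length(h)
  Amat <- function(dt) { e <- exp(-b * dt); matrix(c(1, 0, (1 - e) / b, e), 2, 2) }
  Qmat <- function(dt) {
    e <- exp(-b * dt)
    qx <- s^2 / b^2 * (dt - 2 * (1 - e) / b + (1 - e^2) / (2 * b))
    qxv <- s^2 * (1 - e)^2 / (2 * b^2)
    qv <- s^2 * (1 - e^2) / (2 * b)
    matrix(c(qx, qxv, qxv, qv), 2, 2)
  }
  P <- vector("list", n)
  P[[1]] <- matrix(c(p0x, 0, 0, s^2 / (2 * b)), 2, 2)
  if (n > 1) for (k in 2:n) {
    A <- Amat(h[k] - h[k - 1])
    P[[k]] <- A %*% P[[k - 1]] %*% t(A) + Qmat(h[k] - h[k - 1])
  }
  S <- matrix(0, n, n)  # position-position covariance across times
  for (i in 1:n) {
    S[i, i] <- P[[i]][1, 1]
    Cprev <- P[[i]]
    if (i < n) for (j in (i + 1):n) {
      Cprev <- Cprev %*% t(Amat(h[j] - h[j - 1]))
      S[i, j] <- S[j, i] <- Cprev[1, 1]
    }
  }
  Sy <- S + diag(tau^2, n)
  ch <- chol(Sy)
  ll <- 0
  for (col in list(xy$x, xy$y)) {
    r <- col - col[1]
    z <- backsolve(ch, r, transpose = TRUE)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

# Mann-Whitney AUC (rank statistic, ties counted half).
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  rk <- rank(c(pos, neg))
  (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Great-circle speed (km/h) between consecutive rows of a track.
pair_speeds <- function(track) {
  n <- nrow(track)
  if (n < 2) return(numeric(0))
  d <- geosphere::distHaversine(cbind(track$lon[-n], track$lat[-n]),
                                cbind(track$lon[-1], track$lat[-1]),
                                r = EARTH_R) / 1000
  dt <- diff(as.numeric(track$time)) / 3600
  d / dt
}

# Brute-force speed-filter oracle: the largest subsets of fixes (original
# order) with no consecutive-pair violation; returns a list of index sets.
brute_force_speed_subsets <- function(track, vmax = 5) {
  n <- nrow(track)
  stopifnot(n <= 14)
  best <- list(); best_size <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) < best_size || length(idx) < 2) next
    if (all(pair_speeds(track[idx, , drop = FALSE]) <= vmax)) {
      if (length(idx) > best_size) { best <- list(idx); best_size <- length(idx) }
      else best <- c(best, list(idx))
    }
  }
  best
}

# Exhaustive hierarchy-respecting best-AIC model search (stepwise oracle).
exhaustive_best_aic <- function(table) {
  subsets <- list(character(0), "sst", "depth", c("sst", "sst2"),
                  c("depth", "depth2"), c("sst", "depth"),
                  c("sst", "sst2", "depth"), c("sst", "depth", "depth2"),
                  c("sst", "sst2", "depth", "depth2"))
  fits <- lapply(subsets, function(tm) fit_logistic(table, tm))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  list(terms = subsets[[which.min(aics)]], fit = fits[[which.min(aics)]])
}

# Small all-ocean grid with a deterministic depth ramp, for unit tests.
toy_grid <- function(nx_km = 100, ny_km = 100, cell = 10000,
                     coast = NULL, rate = 2.5, widen_north = 0,
                     lat_band = c(-90, 90), max_depth = 200) {
  ll <- unproject_coordinates(c(0, nx_km * 1000), c(0, ny_km * 1000))
  g <- make_grid(range(ll$lon), range(ll$lat), cell_size = cell, coast = coast)
  g <- make_bathymetry(g, slope = list(rate = rate, max_depth = 320,
                                       widen_north = widen_north))
  apply_study_mask(g, lat_band = lat_band, max_depth = max_depth)
}

# Occurrence table drawn directly from a truth surface over independent
# uniform covariates (no spatial structure), for GLM-focused tests.
glm_fixture <- function(n, truth = default_truth_surface(), seed = 1,
                        sst_range = c(5, 30), depth_range = c(0, 150)) {
  set.seed(seed)
  sst <- runif(n, sst_range[1], sst_range[2])
  dep <- runif(n, depth_range[1], depth_range[2])
  p <- predict_probability(truth, sst, dep)
  tibble::tibble(cell_id = seq_len(n), year = 1L, month = 1L,
                 y = rbinom(n, 1, p), sst_c = sst, depth_m = dep)
}
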