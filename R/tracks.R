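#' Iterative speed filter for telemetry fixes
#'
#' Removes errant fixes whose implied travel speed against a neighbour
#' exceeds `vmax` (default 5 km/h, the standard cap for hard-shelled sea
#' turtles). Speeds are great-circle distance over elapsed time on the raw
#' lon/lat fixes. The filter repeatedly deletes the single fix whose removal
#' most reduces the number of violating consecutive pairs (ties broken by
#' removing the later fix) until no pair violates the bound; retained fixes
#' are a subset of the input in original order.
#'
#' @param track a `raw_track` (or any data frame with `time`, `lon`, `lat`).
#' @param vmax maximum allowed speed, km/h.
#' @return the filtered track; removed row indices in `attr(, "removed")`.
#' @export
speed_filter <- function(track, vmax = 5) {
  assert_that(nrow(track) >= 2, "speed filter needs at least 2 fixes")
  tt <- as.numeric(track$time)
  assert_that(all(diff(tt) > 0), "fix times must be strictly increasing")
  keep <- seq_len(nrow(track))
  speed_between <- function(i, j) {
    d <- geosphere::distHaversine(c(track$lon[i], track$lat[i]),
                                  c(track$lon[j], track$lat[j]),
                                  r = BT_EARTH_RADIUS)
    (d / 1000) / ((tt[j] - tt[i]) / 3600)
  }
  pair_viol <- function(idx) {
    if (length(idx) < 2) return(logical(0))
    v <- vapply(seq_len(length(idx) - 1),
                function(k) speed_between(idx[k], idx[k + 1]), numeric(1))
    v > vmax
  }
  viol <- pair_viol(keep)
  while (any(viol)) {
    # candidates: fixes touching a violating pair
    cand <- unique(c(which(viol), which(viol) + 1))
    n_now <- sum(viol)
    best <- NULL; best_red <- -Inf
    for (ci in cand) {
      # local change: pairs (ci-1,ci) and (ci,ci+1) go, (ci-1,ci+1) appears
      lost <- 0
      if (ci > 1) lost <- lost + viol[ci - 1]
      if (ci < length(keep)) lost <- lost + viol[ci]
      gained <- if (ci > 1 && ci < length(keep))
        speed_between(keep[ci - 1], keep[ci + 1]) > vmax else FALSE
      red <- lost - gained
      if (red > best_red || (red == best_red && keep[ci] > keep[best])) {
        best <- ci; best_red <- red
      }
    }
    keep <- keep[-best]
    if (length(keep) < 2)
      stop_bt("speed filter removed essentially the whole track")
    viol <- pair_viol(keep)
  }
  out <- track[keep, , drop = FALSE]
  attr(out, "removed") <- setdiff(seq_len(nrow(track)), keep)
  out
}

#' Project a track into planar coordinates
#'
#' @param track a `raw_track`.
#' @param center,azimuth see [project_coordinates()].
#' @return a `track_xy` tibble with `time`, `hours` (since first fix), `x`,
#'   `y` (m).
#' @export
track_to_xy <- function(track, center = c(-75, 35), azimuth = 90) {
  xy <- project_coordinates(track$lon, track$lat, center = center,
                            azimuth = azimuth)
  out <- tibble::tibble(
    time = track$time,
    hours = as.numeric(difftime(track$time, track$time[1], units = "hours")),
    x = xy$x, y = xy$y)
  structure(out, class = c("track_xy", class(out)),
            animal_id = if ("animal_id" %in% names(track)) track$animal_id[1] else NA_character_,
            center = center, azimuth = azimuth)
}

# --- CTCRW state space ------------------------------------------------------
#
# Integrated Ornstein-Uhlenbeck velocity model per axis: state (position,
# velocity), velocity mean-reverts to 0 at rate `reversion` (1/h) with
# innovation magnitude `diffusion` (m h^-3/2); observations are position
# plus isotropic N(0, obs_error_sd^2) error. The two axes share the same
# covariance recursions, so the filter propagates one covariance and two
# mean vectors. Initial state at the first fix: position ~ N(first
# observation, BT_P0X), velocity ~ its stationary distribution.

BT_P0X <- 1e6  # initial position variance, m^2 (1 km sd)

ctcrw_transition <- function(b, s, dt) {
  e <- exp(-b * dt)
  list(a12 = (1 - e) / b, a22 = e,
       qx = s^2 / b^2 * (dt - 2 * (1 - e) / b + (1 - e^2) / (2 * b)),
       qxv = s^2 * (1 - e)^2 / (2 * b^2),
       qv = s^2 * (1 - e^2) / (2 * b))
}

check_ctcrw_params <- function(params) {
  b <- params$reversion; s <- params$diffusion; tau <- params$obs_error_sd
  assert_that(is.numeric(b) && is.finite(b) && b > 0, "reversion must be > 0")
  assert_that(is.numeric(s) && is.finite(s) && s >= 0, "diffusion must be >= 0")
  assert_that(is.numeric(tau) && is.finite(tau) && tau >= 0,
              "obs_error_sd must be >= 0")
  invisible(params)
}

# Shared Kalman forward pass. Returns the log-likelihood and, if store =
# TRUE, the per-step filtered/predicted moments needed by the smoother.
# obs is a logical flag per time: FALSE rows are prediction-only times.
ctcrw_filter <- function(hours, yx, yy, obs, params, store = FALSE) {
  check_ctcrw_params(params)
  b <- params$reversion; s <- params$diffusion; tau2 <- params$obs_error_sd^2
  n <- length(hours)
  mx <- c(yx[which(obs)[1]], 0); my <- c(yy[which(obs)[1]], 0)
  P <- c(BT_P0X, 0, s^2 / (2 * b))  # (Pxx, Pxv, Pvv)
  ll <- 0
  if (store) {
    Mxf <- Myf <- matrix(0, n, 2); Pf <- matrix(0, n, 3)
    Mxp <- Myp <- matrix(0, n, 2); Pp <- matrix(0, n, 3)
    A12 <- numeric(n)
  }
  for (k in seq_len(n)) {
    if (k > 1) {
      tr <- ctcrw_transition(b, s, hours[k] - hours[k - 1])
      mx <- c(mx[1] + tr$a12 * mx[2], tr$a22 * mx[2])
      my <- c(my[1] + tr$a12 * my[2], tr$a22 * my[2])
      Pxx <- P[1] + 2 * tr$a12 * P[2] + tr$a12^2 * P[3] + tr$qx
      Pxv <- tr$a22 * (P[2] + tr$a12 * P[3]) + tr$qxv
      Pvv <- tr$a22^2 * P[3] + tr$qv
      P <- c(Pxx, Pxv, Pvv)
      if (store) A12[k] <- tr$a12
    }
    if (store) { Mxp[k, ] <- mx; Myp[k, ] <- my; Pp[k, ] <- P }
    if (obs[k]) {
      S <- P[1] + tau2
      if (!is.finite(S) || S <= 0)
        stop_bt("singular innovation covariance in the CTCRW filter")
      rx <- yx[k] - mx[1]; ry <- yy[k] - my[1]
      ll <- ll - 0.5 * (2 * log(2 * pi * S) + (rx^2 + ry^2) / S)
      K <- c(P[1], P[2]) / S
      mx <- mx + K * rx; my <- my + K * ry
      P <- c(P[1] - K[1] * P[1], P[2] - K[1] * P[2], P[3] - K[2] * P[2])
    }
    if (store) { Mxf[k, ] <- mx; Myf[k, ] <- my; Pf[k, ] <- P }
  }
  if (!store) return(ll)
  list(ll = ll, Mxf = Mxf, Myf = Myf, Pf = Pf,
       Mxp = Mxp, Myp = Myp, Pp = Pp, A12 = A12)
}

#' CTCRW log-likelihood of a projected track
#'
#' Exact Gaussian log-likelihood of the observed fixes under the
#' continuous-time correlated random walk, computed by a Kalman filter with
#' the exact integrated-OU transition over each irregular time gap.
#'
#' @param xy a `track_xy` from [track_to_xy()] (or a data frame with
#'   `hours`, `x`, `y`).
#' @param params list with `reversion` (1/h), `diffusion` (m h^-3/2) and
#'   `obs_error_sd` (m).
#' @return the log-likelihood (both axes combined).
#' @export
ctcrw_loglik <- function(xy, params) {
  assert_that(nrow(xy) >= 2, "need at least 2 fixes")
  assert_that(all(diff(xy$hours) > 0), "fix times must be strictly increasing")
  ctcrw_filter(xy$hours, xy$x, xy$y, rep(TRUE, nrow(xy)), params)
}

#' Fit the CTCRW by maximum likelihood
#'
#' Maximises [ctcrw_loglik()] over log-transformed parameters
#' (Nelder-Mead search followed by a BFGS polish), with deterministic
#' jittered restarts if the search fails. Standard errors come from the
#' numerically evaluated Hessian on the log scale.
#'
#' @param xy a `track_xy`.
#' @param init optional named list of starting values (`reversion`,
#'   `diffusion`, `obs_error_sd`); sensible data-driven defaults otherwise.
#' @param max_restarts jittered restarts after a failed search.
#' @param seed seed for the restart jitter.
#' @return a `ctcrw_fit`: list with `params` (natural scale), `se`
#'   (delta-method), `vcov_log`, `log_likelihood`, `converged`,
#'   `grad_norm`, `n_restarts`.
#' @export
fit_ctcrw <- function(xy, init = NULL, max_restarts = 3, seed = 1L) {
  assert_that(nrow(xy) >= 4, "too few fixes to fit a CTCRW")
  if (is.null(init)) {
    dt <- diff(xy$hours)
    inc <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
    v_scale <- stats::median(inc / dt) + 1e-6
    init <- list(reversion = 0.5 / stats::median(dt),
                 diffusion = v_scale, obs_error_sd = 0.3 * stats::median(inc) + 1)
  }
  theta0 <- log(pmax(unlist(init[c("reversion", "diffusion", "obs_error_sd")]),
                     1e-8))
  nll <- function(theta) {
    p <- list(reversion = exp(theta[1]), diffusion = exp(theta[2]),
              obs_error_sd = exp(theta[3]))
    v <- tryCatch(-ctcrw_loglik(xy, p), error = function(e) NA_real_)
    if (!is.finite(v)) 1e12 else v
  }
  run_from <- function(th) {
    o1 <- stats::optim(th, nll, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-12))
    stats::optim(o1$par, nll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 200, reltol = 1e-12))
  }
  jitters <- with_seed(seed,
    lapply(seq_len(max_restarts), function(i) stats::rnorm(3, 0, 0.7)))
  best <- NULL; tries <- 0
  for (r in 0:max_restarts) {
    th <- if (r == 0) theta0 else theta0 + jitters[[r]]
    fit <- tryCatch(run_from(th), error = function(e) NULL)
    tries <- r
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e11) {
      if (is.null(best) || fit$value < best$value - 1e-8) best <- fit
      if (fit$convergence == 0) break
    }
  }
  if (is.null(best)) {
    warning("CTCRW fit failed to converge after restarts; returning init")
    return(structure(list(params = init, se = NULL, vcov_log = NULL,
                          log_likelihood = NA_real_, converged = FALSE,
                          grad_norm = NA_real_, n_restarts = tries),
                     class = "ctcrw_fit"))
  }
  th <- best$par
  # central-difference score norm at the optimum
  g <- vapply(1:3, function(i) {
    h <- 1e-5 * max(1, abs(th[i]))
    e <- numeric(3); e[i] <- h
    (nll(th + e) - nll(th - e)) / (2 * h)
  }, numeric(1))
  vcov_log <- tryCatch(solve(best$hessian), error = function(e) NULL)
  pars <- stats::setNames(exp(th), c("reversion", "diffusion", "obs_error_sd"))
  se <- if (!is.null(vcov_log) && all(diag(vcov_log) > 0))
    pars * sqrt(diag(vcov_log)) else NULL
  structure(list(params = as.list(pars), se = se, vcov_log = vcov_log,
                 log_likelihood = -best$value,
                 converged = best$convergence == 0 && sqrt(sum(g^2)) < 1e-2,
                 grad_norm = sqrt(sum(g^2)), n_restarts = tries),
            class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat("<ctcrw_fit> logLik", round(x$log_likelihood, 2),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(unlist(x$params))
  invisible(x)
}

#' Daily interpolation by Kalman smoothing
#'
#' Evaluates the smoothed (Rauch-Tung-Striebel, not filtered) state means
#' and variances of the fitted CTCRW at daily 00:00 UTC instants spanning
#' the track. Uncertainty grows inside observation gaps and shrinks near
#' fixes.
#'
#' @param xy a `track_xy`.
#' @param params CTCRW parameters (a `ctcrw_fit` or its `params` list).
#' @return a `fitted_track`: tibble with `date`, `x`, `y`, `sd_x`, `sd_y`.
#' @export
interpolate_daily <- function(xy, params) {
  if (inherits(params, "ctcrw_fit")) params <- params$params
  assert_that(nrow(xy) >= 2, "need at least 2 fixes")
  t0 <- xy$time[1]
  day0 <- as.POSIXct(trunc(t0, "days"), tz = "UTC")
  if (day0 < t0) day0 <- day0 + 86400
  last <- xy$time[nrow(xy)]
  if (day0 > last) stop_bt("track spans less than one daily instant")
  days <- seq(day0, last, by = 86400)
  dh <- as.numeric(difftime(days, t0, units = "hours"))
  sm <- ctcrw_smooth(xy, params, at_hours = dh)
  structure(tibble::tibble(date = as.Date(days), x = sm$x, y = sm$y,
                           sd_x = sm$sd, sd_y = sm$sd),
            class = c("fitted_track", "tbl_df", "tbl", "data.frame"),
            animal_id = attr(xy, "animal_id"), params = params)
}

# Smoothed position mean/sd at arbitrary times (hours from first fix).
ctcrw_smooth <- function(xy, params, at_hours) {
  obs_h <- xy$hours
  all_h <- sort(unique(c(obs_h, at_hours)))
  is_obs <- all_h %in% obs_h
  idx <- match(all_h, obs_h)
  yx <- ifelse(is_obs, xy$x[idx], 0)
  yy <- ifelse(is_obs, xy$y[idx], 0)
  f <- ctcrw_filter(all_h, yx, yy, is_obs, params, store = TRUE)
  n <- length(all_h)
  Mx <- f$Mxf; My <- f$Myf; Ps <- f$Pf
  mx_s <- f$Mxf[n, ]; my_s <- f$Myf[n, ]; P_s <- f$Pf[n, ]
  Sx <- matrix(0, n, 2); Sy <- matrix(0, n, 2); SP <- matrix(0, n, 3)
  Sx[n, ] <- mx_s; Sy[n, ] <- my_s; SP[n, ] <- P_s
  for (k in (n - 1):1) {
    if (n < 2) break
    a12 <- f$A12[k + 1]
    # C = P_f[k] A' inv(P_p[k+1]); A = [1 a12; 0 a22]
    Pf <- f$Pf[k, ]; Pp <- f$Pp[k + 1, ]
    a22 <- exp(-params$reversion * (all_h[k + 1] - all_h[k]))
    # P_f A' with A' = [1 0; a12 a22]
    B11 <- Pf[1] + a12 * Pf[2]; B12 <- a22 * Pf[2]
    B21 <- Pf[2] + a12 * Pf[3]; B22 <- a22 * Pf[3]
    det <- Pp[1] * Pp[3] - Pp[2]^2
    if (det <= 0) det <- max(det, 1e-12)
    C11 <- (B11 * Pp[3] - B12 * Pp[2]) / det
    C12 <- (-B11 * Pp[2] + B12 * Pp[1]) / det
    C21 <- (B21 * Pp[3] - B22 * Pp[2]) / det
    C22 <- (-B21 * Pp[2] + B22 * Pp[1]) / det
    dx <- Sx[k + 1, ] - f$Mxp[k + 1, ]
    dy <- Sy[k + 1, ] - f$Myp[k + 1, ]
    Sx[k, ] <- f$Mxf[k, ] + c(C11 * dx[1] + C12 * dx[2], C21 * dx[1] + C22 * dx[2])
    Sy[k, ] <- f$Myf[k, ] + c(C11 * dy[1] + C12 * dy[2], C21 * dy[1] + C22 * dy[2])
    # P_s[k] = P_f + C (P_s[k+1] - P_p[k+1]) C'
    D <- SP[k + 1, ] - f$Pp[k + 1, ]  # (D11, D12, D22)
    E11 <- C11 * D[1] + C12 * D[2]; E12 <- C11 * D[2] + C12 * D[3]
    E21 <- C21 * D[1] + C22 * D[2]; E22 <- C21 * D[2] + C22 * D[3]
    SP[k, ] <- c(Pf[1] + E11 * C11 + E12 * C12,
                 Pf[2] + E11 * C21 + E12 * C22,
                 Pf[3] + E21 * C21 + E22 * C22)
  }
  at <- match(at_hours, all_h)
  list(x = Sx[at, 1], y = Sy[at, 1], sd = sqrt(pmax(0, SP[at, 1])))
}

#' Clean, fit and interpolate one raw track
#'
#' Convenience wrapper chaining [speed_filter()], [track_to_xy()],
#' [fit_ctcrw()] and [interpolate_daily()].
#'
#' @param track a `raw_track`.
#' @param vmax speed-filter bound (km/h).
#' @param center,azimuth projection parameters.
#' @param ... passed to [fit_ctcrw()].
#' @return a `fitted_track` with the `ctcrw_fit` in `attr(, "fit")`.
#' @export
process_track <- function(track, vmax = 5, center = c(-75, 35), azimuth = 90,
                          ...) {
  filt <- speed_filter(track, vmax = vmax)
  xy <- track_to_xy(filt, center = center, azimuth = azimuth)
  fit <- fit_ctcrw(xy, ...)
  daily <- interpolate_daily(xy, fit)
  attr(daily, "fit") <- fit
  daily
}
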