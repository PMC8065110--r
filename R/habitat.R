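#' Fit the quadratic bathythermal logistic model
#'
#' Maximum-likelihood fit of the Bernoulli presence model
#' `logit(p) = b0 + b1*SST + b2*SST^2 + b3*Depth + b4*Depth^2`
#' (or any hierarchy-respecting subset of its terms) by Newton/IRLS with
#' step-halving. Covariates are standardised internally for numerical
#' conditioning and the coefficients and covariance are back-transformed to
#' natural units (degC, m), so the reported betas are on the scale of the
#' model equation. Convergence requires the score norm (standardised scale)
#' to fall below `tol` with a positive-definite negative Hessian; the
#' default tolerance sits well inside the 1e-6 requirement so independent
#' IRLS implementations agree with the returned coefficients to better
#' than 1e-6.
#'
#' @param table an `occurrence_table` (needs `y`, `sst_c`, `depth_m`).
#' @param terms character subset of `c("sst", "sst2", "depth", "depth2")`;
#'   a quadratic term requires its linear term.
#' @param tol convergence tolerance on the score norm.
#' @param max_iter Newton iteration cap.
#' @return a `habitat_fit`: list with `beta` (natural scale, named), `vcov`,
#'   `log_likelihood`, `aic`, `null_deviance`, `residual_deviance`,
#'   `pct_deviance_explained`, `converged`, `score_norm`, `terms`, `n`.
#' @export
fit_logistic <- function(table, terms = c("sst", "sst2", "depth", "depth2"),
                         tol = 1e-8, max_iter = 60) {
  terms <- as.character(terms)
  bad <- setdiff(terms, c("sst", "sst2", "depth", "depth2"))
  assert_that(length(bad) == 0,
              paste("unknown terms:", paste(bad, collapse = ", ")))
  if ("sst2" %in% terms && !("sst" %in% terms))
    stop_bt("term hierarchy violated: sst2 requires sst")
  if ("depth2" %in% terms && !("depth" %in% terms))
    stop_bt("term hierarchy violated: depth2 requires depth")
  y <- table$y
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  assert_that(any(y == 1) && any(y == 0),
              "need at least one presence and one absence")
  n <- length(y)
  mS <- mean(table$sst_c); sS <- stats::sd(table$sst_c)
  mD <- mean(table$depth_m); sD <- stats::sd(table$depth_m)
  if (!is.finite(sS) || sS == 0) sS <- 1
  if (!is.finite(sD) || sD == 0) sD <- 1
  zs <- (table$sst_c - mS) / sS
  zd <- (table$depth_m - mD) / sD
  cols <- list("(Intercept)" = rep(1, n))
  if ("sst" %in% terms) cols$sst <- zs
  if ("sst2" %in% terms) cols$sst2 <- zs^2
  if ("depth" %in% terms) cols$depth <- zd
  if ("depth2" %in% terms) cols$depth2 <- zd^2
  X <- do.call(cbind, cols)
  p_names <- names(cols)
  a <- numeric(ncol(X))
  a[1] <- stats::qlogis(mean(y))
  loglik <- function(a) {
    eta <- drop(X %*% a)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(a)
  converged <- FALSE
  score_norm <- NA_real_
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% a)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    w <- p * (1 - p)
    H <- crossprod(X * sqrt(w))
    score_norm <- sqrt(sum(score^2))
    if (score_norm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the log-likelihood non-decreasing
    lam <- 1
    repeat {
      a_new <- a + lam * step
      ll_new <- loglik(a_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { a_new <- a; ll_new <- ll; break }
    }
    a <- a_new; ll <- ll_new
  }
  eta <- drop(X %*% a)
  if (!converged) {
    if (max(abs(eta)) > 30)
      warning("possible separation: fitted probabilities pinned at 0/1")
    else
      warning("logistic fit did not reach the score tolerance")
  }
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  H <- crossprod(X * sqrt(w))
  V_a <- tryCatch(solve(H), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  # back-transform standardised coefficients a -> natural beta = T a
  full <- c("(Intercept)", "sst", "sst2", "depth", "depth2")
  Tm <- matrix(0, length(p_names), length(p_names),
               dimnames = list(p_names, p_names))
  Tm["(Intercept)", "(Intercept)"] <- 1
  if ("sst" %in% p_names) {
    Tm["sst", "sst"] <- 1 / sS
    Tm["(Intercept)", "sst"] <- -mS / sS
  }
  if ("sst2" %in% p_names) {
    Tm["sst2", "sst2"] <- 1 / sS^2
    Tm["sst", "sst2"] <- -2 * mS / sS^2
    Tm["(Intercept)", "sst2"] <- mS^2 / sS^2
  }
  if ("depth" %in% p_names) {
    Tm["depth", "depth"] <- 1 / sD
    Tm["(Intercept)", "depth"] <- -mD / sD
  }
  if ("depth2" %in% p_names) {
    Tm["depth2", "depth2"] <- 1 / sD^2
    Tm["depth", "depth2"] <- -2 * mD / sD^2
    Tm["(Intercept)", "depth2"] <- mD^2 / sD^2
  }
  beta <- drop(Tm %*% a)
  names(beta) <- p_names
  vcov_nat <- Tm %*% V_a %*% t(Tm)
  dimnames(vcov_nat) <- list(p_names, p_names)
  pbar <- mean(y)
  null_dev <- -2 * (sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar))
  res_dev <- -2 * ll
  structure(list(beta = beta, vcov = vcov_nat, log_likelihood = ll,
                 aic = -2 * ll + 2 * length(a),
                 null_deviance = null_dev, residual_deviance = res_dev,
                 pct_deviance_explained = 100 * (1 - res_dev / null_dev),
                 converged = converged, score_norm = score_norm,
                 terms = setdiff(p_names, "(Intercept)"), n = n,
                 covariate_center = c(sst = mS, depth = mD),
                 covariate_scale = c(sst = sS, depth = sD)),
            class = "habitat_fit")
}

#' @export
print.habitat_fit <- function(x, ...) {
  cat(sprintf("<habitat_fit> n = %d, logLik = %.2f, AIC = %.2f, %%dev = %.2f%s\n",
              x$n, x$log_likelihood, x$aic, x$pct_deviance_explained,
              if (x$converged) "" else "  [NOT converged]"))
  print(round(x$beta, 6))
  invisible(x)
}

#' Percent deviance explained
#'
#' `100 * (1 - residual_deviance / null_deviance)` of a fit relative to the
#' intercept-only model on the same data.
#'
#' @param fit a `habitat_fit`.
#' @param null_fit optional explicit intercept-only `habitat_fit` on the
#'   same data (checked for matching sample size).
#' @return percent, in `[0, 100]` for maximum-likelihood fits.
#' @export
deviance_explained <- function(fit, null_fit = NULL) {
  nd <- if (is.null(null_fit)) fit$null_deviance else {
    assert_that(null_fit$n == fit$n, "fits are not on the same data")
    null_fit$residual_deviance
  }
  if (nd <= 0) stop_bt("null deviance is zero; deviance explained undefined")
  100 * (1 - fit$residual_deviance / nd)
}

#' Forward stepwise selection over the quadratic terms
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' term (respecting the quadratic hierarchy) that gives the lowest AIC
#' among candidates that both lower the AIC and increase the percent
#' deviance explained relative to the current model; stops when no
#' candidate qualifies.
#'
#' @param table an `occurrence_table`.
#' @param candidate_terms candidate pool.
#' @return list with `fit` (selected `habitat_fit`) and `trace` (tibble of
#'   steps: term added, AIC, percent deviance explained).
#' @export
forward_stepwise <- function(table,
                             candidate_terms = c("sst", "sst2", "depth", "depth2")) {
  prereq <- c(sst2 = "sst", depth2 = "depth")
  current <- character(0)
  fit <- fit_logistic(table, terms = current)
  trace <- tibble::tibble(step = 0L, term_added = "(Intercept)",
                          aic = fit$aic,
                          pct_deviance_explained = fit$pct_deviance_explained)
  step <- 0L
  repeat {
    pool <- setdiff(candidate_terms, current)
    pool <- pool[vapply(pool, function(tm)
      is.na(prereq[tm]) || prereq[tm] %in% current, logical(1))]
    if (length(pool) == 0) break
    fits <- lapply(pool, function(tm) fit_logistic(table, c(current, tm)))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    devs <- vapply(fits, `[[`, numeric(1), "pct_deviance_explained")
    ok <- aics < fit$aic & devs > fit$pct_deviance_explained
    if (!any(ok)) break
    pick <- which(ok)[which.min(aics[ok])]
    current <- c(current, pool[pick])
    fit <- fits[[pick]]
    step <- step + 1L
    trace <- rbind(trace, tibble::tibble(
      step = step, term_added = pool[pick], aic = fit$aic,
      pct_deviance_explained = fit$pct_deviance_explained))
  }
  list(fit = fit, trace = trace)
}

#' Predicted probability of presence
#'
#' Inverse-logit of the fitted linear predictor at given SST and depth;
#' vectorised and recycling over fields. Works for `habitat_fit` and
#' `truth_surface` objects.
#'
#' @param fit a `habitat_fit` (terms absent from the fit contribute 0).
#' @param sst,depth covariate values (degC, m).
#' @return probabilities in `[0, 1]`.
#' @export
predict_probability <- function(fit, sst, depth) {
  b <- if (inherits(fit, "truth_surface")) fit$beta else {
    full <- stats::setNames(numeric(5),
                            c("(Intercept)", "sst", "sst2", "depth", "depth2"))
    full[names(fit$beta)] <- fit$beta
    full
  }
  stats::plogis(b[1] + b[2] * sst + b[3] * sst^2 + b[4] * depth + b[5] * depth^2)
}

#' Peak of the fitted response surface
#'
#' Analytic maximisers of the quadratic logit in each covariate,
#' `-b1 / (2 b2)` and `-b3 / (2 b4)`; NA when the corresponding quadratic
#' term is missing or non-concave.
#'
#' @param fit a `habitat_fit` or `truth_surface`.
#' @return list with `peak_sst` (degC) and `peak_depth` (m).
#' @export
fit_peaks <- function(fit) {
  if (inherits(fit, "truth_surface"))
    return(list(peak_sst = fit$peak_sst, peak_depth = fit$peak_depth))
  b <- fit$beta
  pk <- function(l, q) {
    if (!all(c(l, q) %in% names(b)) || b[q] >= 0) NA_real_
    else unname(-b[l] / (2 * b[q]))
  }
  list(peak_sst = pk("sst", "sst2"), peak_depth = pk("depth", "depth2"))
}

#' Randomised quantile residuals for the Bernoulli fit
#'
#' Dunn-Smyth residuals: for each row, a uniform draw from the interval of
#' the Bernoulli CDF jump at the observed outcome, mapped through the
#' standard-normal quantile function. Under a correctly specified model the
#' residuals are standard normal.
#'
#' @param fit a `habitat_fit`.
#' @param table the `occurrence_table` the fit was computed on.
#' @param seed integer seed for the randomisation.
#' @return numeric residual vector with `mean` and `var` attributes.
#' @export
quantile_residuals <- function(fit, table, seed = NULL) {
  p <- predict_probability(fit, table$sst_c, table$depth_m)
  u <- with_seed(seed, {
    lo <- ifelse(table$y == 1, 1 - p, 0)
    hi <- ifelse(table$y == 1, 1, 1 - p)
    stats::runif(length(p), lo, hi)
  })
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- stats::qnorm(u)
  attr(r, "mean") <- mean(r)
  attr(r, "var") <- stats::var(r)
  r
}
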