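test_that("intercept-only fit reproduces the closed-form prevalence logit", {
  tab <- glm_fixture(1000, seed = 2)
  tab$y <- rep(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 1), 100)  # 30% presences
  f <- fit_logistic(tab, terms = character(0))
  expect_equal(unname(f$beta[1]), qlogis(0.3), tolerance = 1e-9)
  expect_true(f$converged)
  expect_equal(f$pct_deviance_explained, 0, tolerance = 1e-9)
})

test_that("fit matches the independent IRLS oracle on fixtures", {
  for (seed in c(5, 17)) {
    tab <- glm_fixture(200, seed = seed)
    f <- fit_logistic(tab)
    g <- suppressWarnings(
      stats::glm(y ~ sst_c + I(sst_c^2) + depth_m + I(depth_m^2),
                 family = stats::binomial(), data = tab))
    expect_lt(max(abs(f$beta - stats::coef(g))), 1e-6)
    expect_equal(f$aic, stats::AIC(g), tolerance = 1e-9)
    expect_equal(f$residual_deviance, stats::deviance(g), tolerance = 1e-8)
    expect_equal(f$null_deviance, g$null.deviance, tolerance = 1e-8)
    # AIC identity
    expect_equal(f$aic, -2 * f$log_likelihood + 2 * length(f$beta))
  }
  # subset model against the matching glm
  tab <- glm_fixture(300, seed = 23)
  f2 <- fit_logistic(tab, terms = c("depth", "depth2"))
  g2 <- stats::glm(y ~ depth_m + I(depth_m^2), family = stats::binomial(),
                   data = tab)
  expect_lt(max(abs(f2$beta - stats::coef(g2))), 1e-6)
  expect_error(fit_logistic(tab, terms = "sst2"), "hierarchy")
})

test_that("coefficients are recovered within 3 SE at large n", {
  truth <- default_truth_surface()
  tab <- glm_fixture(50000, truth = truth, seed = 41)
  f <- fit_logistic(tab)
  se <- sqrt(diag(f$vcov))
  expect_true(f$converged)
  expect_true(all(abs(f$beta - truth$beta) <= 3 * se))
})

test_that("deviance explained is monotone over nested models", {
  tab <- glm_fixture(2000, seed = 31)
  nested <- list(character(0), "sst", c("sst", "sst2"),
                 c("sst", "sst2", "depth"),
                 c("sst", "sst2", "depth", "depth2"))
  dev <- vapply(nested, function(tm)
    fit_logistic(tab, tm)$pct_deviance_explained, numeric(1))
  expect_true(all(diff(dev) >= -1e-8))
  expect_equal(dev[1], 0, tolerance = 1e-9)
  f <- fit_logistic(tab)
  expect_equal(deviance_explained(f), f$pct_deviance_explained)
  expect_equal(deviance_explained(f, fit_logistic(tab, character(0))),
               f$pct_deviance_explained, tolerance = 1e-6)
})

test_that("coefficients are invariant to affine covariate rescaling", {
  tab <- glm_fixture(1500, seed = 19)
  f1 <- fit_logistic(tab)
  tab2 <- tab
  tab2$sst_c <- tab$sst_c * 1.8 - 4      # e.g. a unit change
  tab2$depth_m <- tab$depth_m / 3.28 + 10
  f2 <- fit_logistic(tab2)
  # identical fitted surfaces: compare predictions on a probe grid
  probe_s <- seq(6, 29, length.out = 40)
  probe_d <- seq(5, 140, length.out = 40)
  p1 <- predict_probability(f1, probe_s, probe_d)
  p2 <- predict_probability(f2, probe_s * 1.8 - 4, probe_d / 3.28 + 10)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("forward stepwise matches exhaustive search and respects signals", {
  # strong full-model signal: all four terms selected, matching brute force
  tab <- glm_fixture(4000, seed = 51)
  sel <- forward_stepwise(tab)
  expect_setequal(sel$fit$terms, c("sst", "sst2", "depth", "depth2"))
  ex <- exhaustive_best_aic(tab)
  expect_setequal(sel$fit$terms, ex$terms)
  expect_equal(sel$fit$aic, ex$fit$aic, tolerance = 1e-8)
  # AIC decreases and deviance explained increases along the trace
  expect_true(all(diff(sel$trace$aic) < 0))
  expect_true(all(diff(sel$trace$pct_deviance_explained) > 0))
  # depth-only generative model: no SST terms selected at large n
  depth_truth <- suppressWarnings(
    truth_surface(c(-2, 0, 0, 0.138, -0.00138)))
  tab_d <- glm_fixture(20000, truth = depth_truth, seed = 52)
  sel_d <- forward_stepwise(tab_d)
  expect_false(any(c("sst", "sst2") %in% sel_d$fit$terms))
  expect_true(all(c("depth", "depth2") %in% sel_d$fit$terms))
})

test_that("predicted surface peaks at the analytic optimum and is symmetric", {
  truth <- default_truth_surface()
  tab <- glm_fixture(30000, truth = truth, seed = 61)
  f <- fit_logistic(tab)
  pk <- fit_peaks(f)
  # grid search agrees with the analytic peak
  ss <- seq(5, 30, by = 0.05)
  ps <- predict_probability(f, ss, pk$peak_depth)
  expect_equal(ss[which.max(ps)], pk$peak_sst, tolerance = 0.06)
  dd <- seq(0, 150, by = 0.1)
  pd <- predict_probability(f, pk$peak_sst, dd)
  expect_equal(dd[which.max(pd)], pk$peak_depth, tolerance = 0.2)
  # quadratic symmetry about the peak at fixed depth
  expect_equal(predict_probability(f, pk$peak_sst + 3, 50),
               predict_probability(f, pk$peak_sst - 3, 50), tolerance = 1e-9)
  # flat model predicts one half everywhere
  flat <- suppressWarnings(truth_surface(rep(0, 5)))
  expect_equal(unname(predict_probability(flat, c(0, 15, 30), c(0, 50, 100))),
               rep(0.5, 3))
})

test_that("randomised quantile residuals are standard normal under the truth", {
  truth <- default_truth_surface()
  tab <- glm_fixture(20000, truth = truth, seed = 71)
  f <- fit_logistic(tab)
  r <- quantile_residuals(f, tab, seed = 72)
  expect_lt(abs(attr(r, "mean")), 0.03)
  expect_gt(attr(r, "var"), 0.95)
  expect_lt(attr(r, "var"), 1.05)
  expect_gt(suppressWarnings(stats::ks.test(r, "pnorm")$p.value), 0.01)
  # same seed, same residuals
  expect_identical(as.numeric(r), as.numeric(quantile_residuals(f, tab, seed = 72)))
  # no residual structure against the covariates under the correct model
  fit_struct <- stats::lm(r ~ tab$sst_c + I(tab$sst_c^2))
  p_ok <- stats::pf(summary(fit_struct)$fstatistic[1], 2, length(r) - 3,
                    lower.tail = FALSE)
  expect_gt(unname(p_ok), 0.01)
  # a grossly misspecified model (omitting the strong SST effect) leaves
  # gross residual structure along the omitted covariate
  f0 <- fit_logistic(tab, terms = c("depth", "depth2"))
  r0 <- quantile_residuals(f0, tab, seed = 73)
  fit_struct0 <- stats::lm(r0 ~ tab$sst_c + I(tab$sst_c^2))
  p_bad <- stats::pf(summary(fit_struct0)$fstatistic[1], 2, length(r0) - 3,
                     lower.tail = FALSE)
  expect_lt(unname(p_bad), 1e-6)
})
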