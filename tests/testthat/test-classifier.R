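test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  set.seed(91)
  for (rep in 1:6) {
    n <- sample(50:400, 1)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0 || sum(labels) == n) next
    scores <- rnorm(n) + labels * runif(1, 0, 2)
    if (rep %% 2 == 0) scores <- round(scores, 1)  # force ties
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, mw_auc(scores, labels), tolerance = 1e-12)
    # exact confusion bookkeeping at every threshold
    P <- r$n_pos; N <- r$n_neg
    tp <- r$points$se * P
    tn <- r$points$sp * N
    expect_equal(tp, round(tp), tolerance = 1e-9)
    expect_equal(tn, round(tn), tolerance = 1e-9)
    expect_true(all(diff(r$points$se) >= 0))  # se grows as threshold drops
    expect_true(all(diff(r$points$sp) <= 0))
  }
})

test_that("ROC limits: perfect separation and uninformative scores", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0)
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, 1)
  cp <- iu_cutpoint(r)
  expect_equal(cp$iu_value, 0)
  expect_equal(cp$se_at_c, 1)
  expect_equal(cp$sp_at_c, 1)
  expect_equal(cp$c, 0.7)  # smallest threshold with Se = Sp = 1
  # labels independent of scores: AUC near one half
  set.seed(92)
  sc <- runif(20000); lb <- rbinom(20000, 1, 0.5)
  expect_equal(roc_curve(sc, lb)$auc, 0.5, tolerance = 0.02)
  expect_error(roc_curve(sc, rep(1, 20000)), "both classes")
})

test_that("IU minimiser matches a brute-force scan and is rank invariant", {
  set.seed(93)
  for (rep in 1:5) {
    scores <- round(runif(10), 2)
    labels <- c(rbinom(9, 1, 0.5), 1 - rbinom(1, 1, 0.5))
    if (sum(labels) %in% c(0, 10)) next
    r <- roc_curve(scores, labels)
    cp <- iu_cutpoint(r)
    # brute force over all candidate thresholds
    iu <- vapply(r$points$threshold, function(t) {
      se <- mean(scores[labels == 1] >= t)
      sp <- mean(scores[labels == 0] < t)
      abs(se - r$auc) + abs(sp - r$auc)
    }, numeric(1))
    expect_equal(cp$iu_value, min(iu), tolerance = 1e-12)
    expect_equal(cp$iu_value,
                 abs(cp$se_at_c - r$auc) + abs(cp$sp_at_c - r$auc))
    # a strictly monotone transform of the scores keeps the same cut index
    r2 <- roc_curve(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels)
    cp2 <- iu_cutpoint(r2)
    expect_equal(cp2$se_at_c, cp$se_at_c)
    expect_equal(cp2$sp_at_c, cp$sp_at_c)
  }
})

test_that("occupancy classification applies the >= rule and preserves NA", {
  p <- c(0.05, 0.08, 0.2, NA)
  expect_equal(classify_occupancy(p, 0.08), c(0L, 1L, 1L, NA_integer_))
  expect_equal(classify_occupancy(p, 0)[1:3], c(1L, 1L, 1L))
  expect_equal(classify_occupancy(c(p[1:3], 1), 1), c(0L, 0L, 0L, 1L))
  # idempotent (classifying a 0/1 field at 0.5 reproduces it) and monotone
  cls <- classify_occupancy(p, 0.08)
  expect_equal(classify_occupancy(cls, 0.5), cls)
  expect_true(all(classify_occupancy(p, 0.2) <= cls, na.rm = TRUE))
  expect_error(classify_occupancy(p, 1.2), "\\[0, 1\\]")
})

test_that("core habitat envelope matches closed-form quadratic roots", {
  truth <- default_truth_surface()
  cutoff <- 0.08
  env <- core_habitat_envelope(truth, cutoff, sst_range = c(0, 35),
                               depth_range = c(0, 200), n = 1401)
  # roots of b0 + b1 s + b2 s^2 + b3 d* + b4 d*^2 = logit(c) at peak depth
  b <- truth$beta
  cc <- b[1] + b[4] * truth$peak_depth + b[5] * truth$peak_depth^2 -
    qlogis(cutoff)
  roots_s <- sort(Re(polyroot(c(cc, b[2], b[3]))))
  expect_equal(env$sst, roots_s, tolerance = 0.05)
  cd <- b[1] + b[2] * truth$peak_sst + b[3] * truth$peak_sst^2 - qlogis(cutoff)
  roots_d <- sort(Re(polyroot(c(cd, b[4], b[5]))))
  expect_equal(env$depth, roots_d, tolerance = 0.2)
  # lowering the cut-point widens the region; raising it towards the
  # maximum shrinks it to the peak
  env_lo <- core_habitat_envelope(truth, 0.02, n = 301)
  expect_lt(env_lo$sst[1], env$sst[1]); expect_gt(env_lo$sst[2], env$sst[2])
  env_hi <- core_habitat_envelope(truth, 0.499, n = 801)
  expect_lt(diff(env_hi$sst), 1)
  expect_equal(mean(env_hi$sst), truth$peak_sst, tolerance = 0.1)
  env_empty <- core_habitat_envelope(truth, 0.9)
  expect_true(env_empty$empty)
})

test_that("top-quartile habitat is a rank property of the field", {
  p <- c(0.1, 0.3, 0.25, 0.9, 0.5, 0.7, 0.2, 0.4)
  tq <- top_quartile_habitat(p)
  expect_equal(sum(tq), 2L)             # 8 distinct values: top 2 flagged
  expect_equal(which(tq == 1), c(4L, 6L))
  # invariant under a monotone transform
  expect_equal(top_quartile_habitat(plogis(5 * p)), tq)
  # sorting oracle on random fields with NA masking
  set.seed(94)
  for (rep in 1:4) {
    f <- runif(50); f[sample(50, 5)] <- NA
    tq2 <- top_quartile_habitat(f)
    q <- quantile(f[!is.na(f)], 0.75, type = 7)
    expect_equal(tq2, ifelse(is.na(f), NA_integer_, as.integer(f >= q)))
  }
  expect_warning(top_quartile_habitat(rep(0.3, 6)), "constant")
  expect_error(top_quartile_habitat(c(0.2, 0.4, NA, NA)), "at least 4")
})
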