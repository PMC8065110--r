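#' ROC curve with exact confusion-matrix bookkeeping
#'
#' Builds the receiver operating characteristic of a score against binary
#' labels. Candidate thresholds are the unique observed scores; a
#' prediction is positive iff `score >= threshold`. Sensitivity and
#' specificity are computed by exact counting and the AUC by the
#' trapezoidal rule over the full curve (equivalently, the Mann-Whitney
#' rank statistic with ties counted half).
#'
#' @param scores numeric vector (e.g. fitted probabilities).
#' @param labels 0/1 vector of the same length, both classes present.
#' @return a `roc_curve`: list with `points` (tibble `threshold`, `se`,
#'   `sp`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "length mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop_bt("ROC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  r <- rle(s)
  thr <- r$values
  last <- cumsum(r$lengths)       # last index of each tie block
  tp <- cumsum(l)[last]           # positives with score >= threshold
  fp <- cumsum(1 - l)[last]
  se <- tp / P
  sp <- (N - fp) / N              # negatives with score < threshold
  # trapezoid over (FPR, TPR), anchored at (0,0) and closing at (1,1)
  fpr <- c(0, fp / N, 1)
  tpr <- c(0, tp / P, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = tibble::tibble(threshold = thr, se = se, sp = sp),
                 auc = auc, n_pos = P, n_neg = N),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d pos / %d neg, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Index-of-Union optimal cut-point
#'
#' Minimises `IU(c) = |Se(c) - AUC| + |Sp(c) - AUC|` exhaustively over the
#' candidate thresholds of a [roc_curve()]. Ties (within 1e-12) are broken
#' by the threshold minimising `|Se - Sp|`, then by the smaller threshold.
#'
#' @param roc a `roc_curve`.
#' @return a `cutpoint_result`: list with `c`, `iu_value`, `se_at_c`,
#'   `sp_at_c`, `auc`.
#' @export
iu_cutpoint <- function(roc) {
  assert_that(inherits(roc, "roc_curve"), "roc must be a roc_curve")
  pts <- roc$points
  iu <- abs(pts$se - roc$auc) + abs(pts$sp - roc$auc)
  cand <- which(iu <= min(iu) + 1e-12)
  bal <- abs(pts$se[cand] - pts$sp[cand])
  cand <- cand[bal <= min(bal) + 1e-12]
  pick <- cand[which.min(pts$threshold[cand])]
  structure(list(c = pts$threshold[pick], iu_value = iu[pick],
                 se_at_c = pts$se[pick], sp_at_c = pts$sp[pick],
                 auc = roc$auc),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint> c = %.4f (IU = %.4f, Se = %.3f, Sp = %.3f, AUC = %.3f)\n",
              x$c, x$iu_value, x$se_at_c, x$sp_at_c, x$auc))
  invisible(x)
}

#' Classify a probability field into occupancy
#'
#' `1` where probability `>= c`, `0` below, `NA` preserved (masked cells
#' carry a missing flag, never an absence).
#'
#' @param prob_field numeric vector/matrix/array of probabilities in
#'   `[0, 1]` with NA for masked cells.
#' @param c cut-point in `[0, 1]`.
#' @return integer field of the same shape.
#' @export
classify_occupancy <- function(prob_field, c) {
  assert_that(length(c) == 1 && is.finite(c) && c >= 0 && c <= 1,
              "cut-point must be a single value in [0, 1]")
  v <- prob_field[is.finite(prob_field)]
  assert_that(all(v >= 0 & v <= 1), "probabilities must lie in [0, 1]")
  out <- prob_field
  out[] <- ifelse(is.na(prob_field), NA_integer_,
                  as.integer(prob_field >= c))
  out
}

#' Core-habitat envelope in covariate space
#'
#' Evaluates the fitted surface on a fine SST x depth grid and returns the
#' bounding intervals of the region with predicted probability `>= c` (the
#' core habitat), together with the evaluated region for plotting.
#'
#' @param fit a `habitat_fit` or `truth_surface`.
#' @param c occupancy cut-point.
#' @param sst_range,depth_range covariate ranges to scan.
#' @param n grid resolution per axis.
#' @return list with `sst` and `depth` intervals (NA if the region is
#'   empty), `empty`, and the evaluation `grid` (tibble `sst`, `depth`,
#'   `prob`, `core`).
#' @export
core_habitat_envelope <- function(fit, c, sst_range = c(0, 35),
                                  depth_range = c(0, 200), n = 401) {
  ss <- seq(sst_range[1], sst_range[2], length.out = n)
  dd <- seq(depth_range[1], depth_range[2], length.out = n)
  g <- expand.grid(sst = ss, depth = dd)
  g$prob <- as.numeric(predict_probability(fit, g$sst, g$depth))
  g$core <- g$prob >= c
  if (!any(g$core))
    return(list(sst = c(NA_real_, NA_real_), depth = c(NA_real_, NA_real_),
                empty = TRUE, grid = tibble::as_tibble(g)))
  list(sst = range(g$sst[g$core]), depth = range(g$depth[g$core]),
       empty = FALSE, grid = tibble::as_tibble(g))
}

#' Top-quartile habitat
#'
#' Flags the cells whose probability is at or above the 75th percentile of
#' the unmasked cell values (inclusive linear-interpolation quantile,
#' R type 7).
#'
#' @param prob_field numeric field with NA for masked cells.
#' @return integer field: 1 = top-quartile habitat, 0 otherwise, NA masked.
#' @export
top_quartile_habitat <- function(prob_field) {
  v <- prob_field[is.finite(prob_field)]
  assert_that(length(v) >= 4, "need at least 4 unmasked cells")
  if (diff(range(v)) == 0)
    warning("constant probability field: all unmasked cells flagged")
  q <- stats::quantile(v, 0.75, type = 7, names = FALSE)
  out <- prob_field
  out[] <- ifelse(is.na(prob_field), NA_integer_,
                  as.integer(prob_field >= q))
  out
}
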