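# Evaluation statistics implemented from first principles: Mann-Whitney
# auROC, DeLong variance / CI / paired test via per-case structural
# components, average precision, exact (binomial) McNemar test, thresholded
# confusion metrics and Bonferroni adjustment.

.check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  labels
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Mean over all (positive, negative) pairs of the indicator that the
#' positive scores higher, with ties contributing 1/2.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 = positive class).
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- .check_binary(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("auROC requires both classes present")
  }
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong structural components: for each positive, the mean placement
# against all negatives (V10), and symmetrically V01 for each negative.
.delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  psi <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated ROC curves
#'
#' Computes each model's auROC with its DeLong standard error and
#' confidence interval, and the two-sided z-test for the difference between
#' the two auROCs evaluated on the same cases. The variance of an auROC of
#' exactly 1 (no discordance) is zero, in which case the test statistic is
#' undefined and an error is raised.
#'
#' @param scores_a,scores_b score vectors from the two models, aligned to
#'   the same cases.
#' @param labels binary labels (1 = positive).
#' @param conf_level confidence level for the per-model auROC intervals.
#' @return a `paired_test_result` with fields `statistic` (z), `p_value`,
#'   `method = "delong"`, `auc_a`, `auc_b`, `ci_a`, `ci_b`, `se_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels, conf_level = 0.95) {
  labels <- .check_binary(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    stop("degenerate variance: DeLong test undefined ",
         "(identical scores or auROC of 100% with no discordance)")
  }
  z <- (ca$auc - cb$auc) / sqrt(var_diff)
  p <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- function(auc, v) {
    if (v < 0) v <- 0
    c(max(0, auc - zq * sqrt(v)), min(1, auc + zq * sqrt(v)))
  }
  structure(list(
    statistic = z, p_value = p, method = "delong",
    auc_a = ca$auc, auc_b = cb$auc,
    ci_a = ci(ca$auc, var_a), ci_b = ci(cb$auc, var_b),
    se_diff = sqrt(var_diff)
  ), class = "paired_test_result")
}

#' auROC confidence interval by DeLong's method
#'
#' @param scores numeric score vector.
#' @param labels binary labels.
#' @param conf_level confidence level.
#' @return list with `auc`, `se`, `ci` (length-2 vector, clipped to \[0,1\]).
#' @export
auroc_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- .check_binary(labels)
  comp <- .delong_components(scores, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  v <- stats::var(comp$v10) / m + stats::var(comp$v01) / n
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = comp$auc, se = sqrt(v),
       ci = c(max(0, comp$auc - zq * sqrt(v)), min(1, comp$auc + zq * sqrt(v))))
}

#' Exact McNemar test on discordant pairs
#'
#' Two-sided exact binomial test: with `b` cases that only classifier A got
#' right and `c` that only classifier B got right, the p-value is
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`; with no
#' discordant pairs the p-value is 1.
#'
#' @param b,c non-negative discordant-pair counts.
#' @return a `paired_test_result` with `statistic = b - c`, `p_value`,
#'   `method = "mcnemar_exact"`.
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stop("b and c must be non-negative integers")
  }
  n <- b + c
  p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  structure(list(statistic = b - c, p_value = p, method = "mcnemar_exact"),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat("<paired_test_result> method =", x$method,
      " statistic =", signif(x$statistic, 5),
      " p =", signif(x$p_value, 5), "\n")
  if (!is.null(x$adjusted_p)) cat("  Bonferroni-adjusted p =", signif(x$adjusted_p, 5), "\n")
  invisible(x)
}

#' Bonferroni adjustment for a paired test result
#'
#' @param result a `paired_test_result`.
#' @param m number of comparisons in the family.
#' @return the result with an `adjusted_p = min(1, m * p)` field.
#' @export
bonferroni_adjust <- function(result, m) {
  stopifnot(inherits(result, "paired_test_result"), m >= 1)
  result$adjusted_p <- min(1, m * result$p_value)
  result
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision form: the sum over descending-score thresholds of
#' precision times the recall increment. Tied scores are treated as a
#' single threshold.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (at least one positive).
#' @return average precision in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- .check_binary(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("average precision requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # last index of each tied-score block
  block_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  precision <- tp[block_end] / (tp[block_end] + fp[block_end])
  recall <- tp[block_end] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Thresholded classification metrics
#'
#' Confusion counts with `score >= threshold` predicting the positive
#' class; precision is reported as `NA` (absent) when no case is predicted
#' positive, and F1 follows suit.
#'
#' @param scores numeric score vector.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`,
#'   `accuracy`, `threshold`.
#' @export
thresholded_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- .check_binary(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
       recall = recall, f1 = f1, accuracy = (tp + tn) / length(labels),
       threshold = threshold)
}

#' Full evaluation report for one score vector
#'
#' @param scores numeric score vector.
#' @param labels binary labels.
#' @param threshold decision threshold for the confusion metrics.
#' @param conf_level confidence level for the auROC interval.
#' @return an `eval_report` list: `auroc`, `auroc_ci`, `auprc`, thresholded
#'   metrics, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5,
                            conf_level = 0.95) {
  labels <- .check_binary(labels)
  ci <- auroc_ci(scores, labels, conf_level)
  tm <- thresholded_metrics(scores, labels, threshold)
  structure(c(list(
    auroc = ci$auc, auroc_ci = ci$ci, auprc = auprc(scores, labels)
  ), tm, list(n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))),
  class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d (%d pos / %d neg)\n  auROC %.4f [%.4f, %.4f]  auPRC %.4f\n",
    x$n_pos + x$n_neg, x$n_pos, x$n_neg, x$auroc, x$auroc_ci[1], x$auroc_ci[2],
    x$auprc
  ))
  cat(sprintf(
    "  @%.2f precision %.4f recall %.4f F1 %.4f accuracy %.4f\n",
    x$threshold, x$precision, x$recall, x$f1, x$accuracy
  ))
  invisible(x)
}

#' Empirical ROC curve points
#'
#' @param scores numeric score vector.
#' @param labels binary labels.
#' @return data frame of (`fpr`, `tpr`, `threshold`) sorted by descending
#'   threshold, including the (0,0) and (1,1) endpoints.
#' @export
roc_points <- function(scores, labels) {
  labels <- .check_binary(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg, 0)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
             threshold = c(Inf, thr, -Inf))
}
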