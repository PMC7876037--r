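# Evaluation metrics and the statistical-test battery used for model
# comparison: accuracy / balanced accuracy / F1 / AUC on a percent scale,
# the corrected resampled t-test for repeated holdout comparisons,
# Holm-Bonferroni adjustment, the Friedman test across feature combinations
# and the Nemenyi post-hoc critical difference.

#' Classification metrics on the percent scale
#'
#' AUC is the rank-statistic (Mann-Whitney) definition computed from the
#' raw scores; accuracy, balanced accuracy (mean of per-class recalls) and
#' F1 are computed from labels thresholded with [classify()]. F1 is
#' reported for the terminated (positive, minority) class; an empty
#' precision/recall denominator yields F1 = 0.
#'
#' @param y binary labels (0/1), both classes present.
#' @param scores numeric score vector.
#' @param threshold decision threshold, default 0.5.
#' @return A `metric_set`: named list `accuracy`, `balanced_accuracy`, `f1`,
#'   `auc`, all in `[0, 100]`.
#' @export
compute_metrics <- function(y, scores, threshold = 0.5) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined: y contains a single class", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- classify(scores, threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  bal <- mean(c(tp / n1, tn / n0))
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(list(
    accuracy = 100 * (tp + tn) / length(y),
    balanced_accuracy = 100 * bal,
    f1 = 100 * f1,
    auc = 100 * auc
  ), class = "metric_set")
}

#' Corrected resampled t-test for repeated holdout comparisons
#'
#' Paired t-test on per-repetition metric differences with the variance
#' inflated by `1/k + n_test/n_train` to account for the overlap of
#' resampled training sets:
#' `t = mean(d) / sqrt((1/k + n_test/n_train) * var(d))`, with k-1 degrees
#' of freedom and a two-sided p-value.
#'
#' @param diffs per-repetition metric differences (length k >= 2).
#' @param n_train,n_test training- and test-set sizes of each repetition.
#' @return List with `t`, `p`, `df` and `zero_variance` (TRUE when the
#'   differences have no variance but a non-zero mean, reported as p -> 0).
#' @export
corrected_resampled_ttest <- function(diffs, n_train, n_test) {
  k <- length(diffs)
  stopifnot(k >= 2, n_train > 0, n_test > 0)
  m <- mean(diffs)
  v <- var(diffs)
  if (v == 0) {
    if (m == 0) {
      return(list(t = 0, p = 1, df = k - 1, zero_variance = FALSE))
    }
    return(list(t = sign(m) * Inf, p = 0, df = k - 1, zero_variance = TRUE))
  }
  t <- m / sqrt((1 / k + n_test / n_train) * v)
  list(t = t, p = 2 * pt(-abs(t), df = k - 1), df = k - 1,
       zero_variance = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "holm"` (step-down
#' multipliers with monotonicity enforcement, clipped at 1).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(pvals) {
  stopifnot(all(pvals >= 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = "holm")
}

#' Friedman test across datasets
#'
#' Ranks the models within every dataset (average ranks on ties) and tests
#' whether the average ranks differ, via [stats::friedman.test()] on the
#' models-by-datasets score matrix. A fully tied matrix (no rank variation
#' anywhere) returns statistic 0 and p = 1.
#'
#' @param score_matrix numeric matrix, rows = models, columns = datasets.
#' @return List with `chi2`, `df`, `p` and `mean_ranks` (average rank per
#'   model; rank 1 = best score).
#' @export
friedman_test <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  k <- nrow(score_matrix)
  N <- ncol(score_matrix)
  stopifnot(k >= 2, N >= 2)
  ranks <- apply(score_matrix, 2, function(col) rank(-col))
  mean_ranks <- rowMeans(ranks)
  if (all(apply(ranks, 2, function(r) all(r == r[1])))) {
    return(list(chi2 = 0, df = k - 1, p = 1, mean_ranks = mean_ranks))
  }
  ft <- stats::friedman.test(t(score_matrix))
  list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, mean_ranks = mean_ranks)
}

# critical values q_alpha(k) for the Nemenyi test (studentized range at
# infinite df divided by sqrt(2)), k = 2..10
NEMENYI_Q <- list(
  "0.05" = c(1.959964, 2.343701, 2.569032, 2.727774, 2.849705,
             2.948319, 3.030879, 3.101730, 3.163684),
  "0.1"  = c(1.644854, 2.052293, 2.291341, 2.459516, 2.588521,
             2.692732, 2.779884, 2.854606, 2.919889)
)

#' Nemenyi post-hoc critical difference
#'
#' The minimum difference in average rank between two of `k` models over
#' `N` datasets that is significant at level `alpha` after a Friedman test:
#' `CD = q_alpha(k) * sqrt(k (k + 1) / (6 N))`, with `q_alpha` from the
#' studentized-range-based Nemenyi table (k <= 10, alpha 0.05 or 0.10).
#'
#' @param k number of models (2..10).
#' @param N number of datasets.
#' @param alpha significance level, 0.05 or 0.10.
#' @return The critical difference (average-rank units).
#' @export
nemenyi_critical_difference <- function(k, N, alpha = 0.05) {
  stopifnot(k >= 2, k <= 10, N >= 1)
  key <- as.character(alpha)
  if (!key %in% names(NEMENYI_Q)) {
    stop("alpha = ", alpha, " is not tabulated; supported levels: ",
         paste(names(NEMENYI_Q), collapse = ", "), call. = FALSE)
  }
  q <- NEMENYI_Q[[key]][k - 1]
  q * sqrt(k * (k + 1) / (6 * N))
}
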