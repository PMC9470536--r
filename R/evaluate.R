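# Calibration and power summaries for the simulation bench.

#' False positive rate with a Wilson confidence interval
#'
#' @param pvalues P-values from null-scenario runs (>= 100 recommended).
#' @param alpha Significance threshold.
#' @return One-row tibble: `rate`, `ci_low`, `ci_high`, `n`.
#' @export
evaluate_fpr <- function(pvalues, alpha = 0.05) {
  pvalues <- pvalues[is.finite(pvalues)]
  n <- length(pvalues)
  if (n == 0) abort("no finite p-values.")
  k <- sum(pvalues <= alpha)
  ci <- wilson_ci(k, n)
  tibble(rate = k / n, ci_low = ci[["lower"]], ci_high = ci[["upper"]],
         n = n)
}

#' True positive rate across significance thresholds
#'
#' @param pvalues P-values from alternative-scenario runs.
#' @param thresholds One or more significance thresholds (e.g.
#'   `10^-(1:8)` for a TPR-versus-threshold curve).
#' @return Tibble with one row per threshold: `threshold`, `tpr`, `n`.
#' @export
evaluate_tpr <- function(pvalues, thresholds = 0.05) {
  pvalues <- pvalues[is.finite(pvalues)]
  if (length(pvalues) == 0) abort("no finite p-values.")
  tibble(threshold = thresholds,
         tpr = vapply(thresholds, function(a) mean(pvalues <= a),
                      numeric(1)),
         n = length(pvalues))
}

#' Area under the ROC curve from null and alternative p-values
#'
#' Mann-Whitney probability that a randomly chosen alternative-scenario
#' P-value is smaller than a randomly chosen null one, with ties counted
#' one half.
#'
#' @param p_null,p_alt Non-empty numeric vectors of P-values.
#' @return Scalar AUC in \[0, 1\].
#' @export
compute_auc <- function(p_null, p_alt) {
  p_null <- p_null[is.finite(p_null)]
  p_alt <- p_alt[is.finite(p_alt)]
  if (length(p_null) == 0 || length(p_alt) == 0) {
    abort("both p-value sets must be non-empty.")
  }
  n0 <- length(p_null)
  n1 <- length(p_alt)
  r <- rank(c(p_null, p_alt))
  # U counts (alt < null) pairs, ties half
  (sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}
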