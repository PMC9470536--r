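# Estimation of theta, the correlation of estimation errors between two
# isoform-eQTL effects. Two routes: from individual-level abundance overlap
# (theta_jk ~= r_p * rho) or, summary-level, from the correlation of effect
# estimates across null SNPs.

#' Error correlation of two isoform-eQTL effects from sample overlap
#'
#' Uses the approximation `theta_jk ~= r_p * rho`, where
#' `rho = n_s / sqrt(n_j * n_k)` measures the sample overlap (`n_s`
#' overlapping individuals out of per-isoform sample sizes `n_j`, `n_k`)
#' and `r_p` is the Pearson correlation of the two isoforms' abundances in
#' the overlapping samples.
#'
#' @param abund_j,abund_k Named numeric vectors of abundance (names are
#'   sample ids).
#' @return One-row tibble: `n_j`, `n_k`, `n_s`, `r_p`, `rho`, `theta`.
#'   With no overlap, `rho = 0`, `theta = 0` and `r_p` is NA.
#' @export
theta_from_overlap <- function(abund_j, abund_k) {
  if (is.null(names(abund_j)) || is.null(names(abund_k))) {
    abort("abundance vectors must carry sample ids as names.")
  }
  shared <- intersect(names(abund_j), names(abund_k))
  n_j <- length(abund_j)
  n_k <- length(abund_k)
  n_s <- length(shared)
  rho <- n_s / sqrt(n_j * n_k)
  if (n_s == 0) {
    return(tibble(n_j = n_j, n_k = n_k, n_s = 0L, r_p = NA_real_,
                  rho = 0, theta = 0))
  }
  if (n_s < 3) {
    abort("fewer than 3 overlapping samples; use theta_from_null_snps().")
  }
  r_p <- cor(abund_j[shared], abund_k[shared])
  tibble(n_j = n_j, n_k = n_k, n_s = n_s, r_p = r_p, rho = rho,
         theta = r_p * rho)
}

# All-pairs theta for isoforms measured on one sample set (rho = 1):
# the Pearson correlation matrix of the abundance columns.
theta_from_abundance <- function(values) {
  th <- cor(values, use = "pairwise.complete.obs")
  nearest_correlation(th)
}

#' Error correlation matrix from null-SNP effect estimates
#'
#' Summary-level estimator of theta: for each isoform pair, the Pearson
#' correlation of effect estimates over SNPs that are null for both
#' isoforms (per-isoform P above `p_threshold`). The pairwise matrix is
#' projected to the nearest valid correlation matrix (pairwise estimates
#' need not be jointly positive semi-definite).
#'
#' @param table Isoform-eQTL summary table for one gene: tibble with
#'   `snp_id`, `isoform_id`, `b`, `p`.
#' @param p_threshold SNPs with P above this in both isoforms count as
#'   null (default 0.01).
#' @param min_null Minimum jointly-null SNPs required per pair (default 30).
#' @return m x m correlation matrix with isoform ids as dimnames.
#' @export
theta_from_null_snps <- function(table, p_threshold = 0.01, min_null = 30) {
  table <- as_tibble(table)
  iso <- sort(unique(table$isoform_id))
  m <- length(iso)
  if (m < 2) abort("need >= 2 isoforms.")
  bw <- tidyr::pivot_wider(table[c("snp_id", "isoform_id", "b")],
                           names_from = "isoform_id", values_from = "b")
  pw <- tidyr::pivot_wider(table[c("snp_id", "isoform_id", "p")],
                           names_from = "isoform_id", values_from = "p")
  B <- as.matrix(bw[iso])
  P <- as.matrix(pw[match(bw$snp_id, pw$snp_id), iso])
  th <- diag(m)
  dimnames(th) <- list(iso, iso)
  for (j in seq_len(m - 1)) {
    for (k in seq.int(j + 1, m)) {
      null_jk <- which(P[, j] > p_threshold & P[, k] > p_threshold &
                         is.finite(B[, j]) & is.finite(B[, k]))
      if (length(null_jk) < min_null) {
        abort(sprintf(
          "only %d jointly-null SNPs for pair (%s, %s); need >= %d",
          length(null_jk), iso[j], iso[k], min_null))
      }
      th[j, k] <- th[k, j] <- cor(B[null_jk, j], B[null_jk, k])
    }
  }
  nearest_correlation(th)
}
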