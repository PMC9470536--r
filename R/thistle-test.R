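# The transcript-level sQTL heterogeneity test. A variant is an sQTL when
# its per-isoform eQTL effects differ between isoforms; the test contrasts
# all pairwise effect differences, accounting for the correlation of their
# estimation errors.

#' Pairwise differences of isoform-eQTL effects and their covariance
#'
#' For a gene with `m` isoforms tested against one variant, forms the
#' q = m(m-1)/2 pairwise effect differences `d_jk = b_j - b_k` (pairs in
#' lexicographic order, j < k) together with their covariance matrix `V`:
#' `var(d_jk) = S_j^2 + S_k^2 - 2 theta_jk S_j S_k` and, for two pairs
#' (j,k), (g,h), `cov(d_jk, d_gh) = cov(b_j,b_g) - cov(b_j,b_h) -
#' cov(b_k,b_g) + cov(b_k,b_h)` with `cov(b_j,b_k) = theta_jk S_j S_k`.
#'
#' @param b Numeric vector of isoform-eQTL effect estimates (length m >= 2).
#' @param se Positive standard errors of `b` (length m).
#' @param theta m x m correlation matrix of the estimation errors of `b`
#'   (see [theta_from_overlap()] and [theta_from_null_snps()]).
#' @return An object of class `thistle_diff`: a list with `d` (length-q
#'   difference vector), `V` (q x q covariance), `pairs` (tibble of j, k),
#'   and `m`.
#' @export
pairwise_differences <- function(b, se, theta) {
  m <- length(b)
  if (m < 2) abort("at least 2 isoforms are required.")
  if (length(se) != m) abort("`b` and `se` must have equal length.")
  if (any(!is.finite(b)) || any(!is.finite(se)) || any(se <= 0)) {
    abort("`b` must be finite and `se` strictly positive.")
  }
  check_correlation_matrix(theta, "theta")
  if (nrow(theta) != m) abort("`theta` dimension must match length(b).")

  pairs <- pair_index(m)
  d <- b[pairs$j] - b[pairs$k]
  # cov(b) implied by (se, theta); V = A %*% Sb %*% t(A) with A the
  # pairwise-difference map, equivalent to the four-term expansion.
  Sb <- theta * tcrossprod(se)
  q <- nrow(pairs)
  A <- matrix(0, q, m)
  A[cbind(seq_len(q), pairs$j)] <- 1
  A[cbind(seq_len(q), pairs$k)] <- -1
  V <- A %*% Sb %*% t(A)
  V <- (V + t(V)) / 2
  if (any(diag(V) <= 0)) {
    abort("non-positive var(d_jk); `theta` is not a valid error correlation.")
  }
  structure(list(d = d, V = V, pairs = pairs, m = m), class = "thistle_diff")
}

#' Standardize pairwise differences and extract the eigenvalue spectrum
#'
#' Scales each difference by its standard deviation, `z_jk =
#' d_jk / sqrt(var(d_jk))`, giving `z ~ MVN(0, R)` under the null of no
#' heterogeneity, with `R` the correlation matrix of the differences. The
#' eigenvalues of `R` determine the null distribution of the statistic;
#' those at or below `eig_tol * max(lambda)` are discarded (the pairwise
#' difference map is structurally rank-deficient: rank(R) <= m - 1).
#'
#' @param diff A `thistle_diff` from [pairwise_differences()].
#' @param eig_tol Relative eigenvalue cutoff (default 1e-8).
#' @return An object of class `thistle_std`: list with `z`, `R`,
#'   `lambda` (retained eigenvalues), `m`, `q`.
#' @export
standardize_differences <- function(diff, eig_tol = 1e-8) {
  stopifnot(inherits(diff, "thistle_diff"))
  sd_d <- sqrt(diag(diff$V))
  z <- diff$d / sd_d
  R <- diff$V / tcrossprod(sd_d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > eig_tol * max(lam)]
  structure(list(z = z, R = R, lambda = lam, m = diff$m, q = length(z)),
            class = "thistle_std")
}

#' The heterogeneity statistic
#'
#' `T = z' I z = sum(z^2)`, the unweighted quadratic form in the
#' standardized pairwise differences.
#'
#' @param std A `thistle_std` from [standardize_differences()].
#' @return Non-negative scalar statistic.
#' @export
thistle_statistic <- function(std) {
  stopifnot(inherits(std, "thistle_std"))
  sum(std$z^2)
}

#' Test one gene-variant pair for splicing QTL heterogeneity
#'
#' Composes [pairwise_differences()], [standardize_differences()],
#' [thistle_statistic()] and a tail probability for the resulting quadratic
#' form. Isoforms with missing effect or standard error at this variant are
#' dropped (with the corresponding rows/columns of `theta`); if fewer than
#' two remain, a no-test row is returned with a reason code.
#'
#' @inheritParams pairwise_differences
#' @param gene_id,snp_id Optional identifiers carried into the result.
#' @param method Tail approximation: `"saddlepoint"` (default), `"davies"`
#'   (characteristic-function inversion) or `"montecarlo"`.
#' @param eig_tol Passed to [standardize_differences()].
#' @param n_draws,seed Monte Carlo controls (used when
#'   `method = "montecarlo"`).
#' @return A one-row tibble: `gene_id`, `snp_id`, `m`, `q`, `n_lambda`,
#'   `statistic`, `p`, `method`, `reason` (NA unless the test was skipped).
#' @examples
#' theta <- diag(3)
#' thistle_test(b = c(0.5, -0.2, -0.3), se = rep(0.1, 3), theta = theta)
#' @export
thistle_test <- function(b, se, theta,
                         gene_id = NA_character_, snp_id = NA_character_,
                         method = c("saddlepoint", "davies", "montecarlo"),
                         eig_tol = 1e-8, n_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  keep <- is.finite(b) & is.finite(se) & se > 0
  no_test <- function(reason, m_used) {
    tibble(gene_id = gene_id, snp_id = snp_id, m = m_used, q = NA_integer_,
           n_lambda = NA_integer_, statistic = NA_real_, p = NA_real_,
           method = method, reason = reason)
  }
  if (sum(keep) < 2) return(no_test("fewer_than_2_isoforms", sum(keep)))
  b <- b[keep]
  se <- se[keep]
  theta <- theta[keep, keep, drop = FALSE]

  diff <- pairwise_differences(b, se, theta)
  std <- standardize_differences(diff, eig_tol = eig_tol)
  stat <- thistle_statistic(std)
  p <- switch(method,
    saddlepoint = pvalue_saddlepoint(stat, std$lambda),
    davies = as.numeric(pvalue_davies(stat, std$lambda)),
    montecarlo = pvalue_montecarlo(stat, std$R, n_draws = n_draws,
                                   seed = seed)$p)
  tibble(gene_id = gene_id, snp_id = snp_id, m = length(b), q = std$q,
         n_lambda = length(std$lambda), statistic = stat, p = as.numeric(p),
         method = method, reason = NA_character_)
}
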