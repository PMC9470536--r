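# Internal helpers shared across modules.

# Lexicographic (j < k) pair index for m items; q = m(m-1)/2 rows.
pair_index <- function(m) {
  stopifnot(m >= 2)
  jk <- which(upper.tri(diag(m)), arr.ind = TRUE)
  ord <- order(jk[, "row"], jk[, "col"])
  tibble::tibble(j = jk[ord, "row"], k = jk[ord, "col"])
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Clips negative eigenvalues at zero, reconstructs, and rescales to unit
#' diagonal. Pairwise-estimated correlation matrices (e.g. from null-SNP
#' effect correlations) need not be positive semi-definite; the tail
#' approximations downstream require a valid correlation matrix.
#'
#' @param x Symmetric numeric matrix with unit diagonal intent.
#' @param tol Eigenvalues below `tol` are clipped to `tol`.
#' @return A symmetric positive semi-definite matrix with unit diagonal.
#' @export
nearest_correlation <- function(x, tol = 0) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) >= tol) {
    diag(x) <- 1
    return(x)
  }
  v <- pmax(e$values, tol)
  y <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(y), .Machine$double.eps))
  y <- y / tcrossprod(d)
  y <- (y + t(y)) / 2
  diag(y) <- 1
  y
}

# Wilson 95% score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

# Minor allele frequency from a dosage vector in [0, 2]; NA-tolerant.
maf_from_dosage <- function(dos) {
  f <- mean(dos, na.rm = TRUE) / 2
  if (is.nan(f)) return(NA_real_)
  min(f, 1 - f)
}

# Checks a square matrix is a usable correlation matrix.
check_correlation_matrix <- function(x, what = "theta") {
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort(sprintf("`%s` must be a square matrix.", what))
  }
  if (max(abs(x - t(x))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", what))
  }
  if (max(abs(diag(x) - 1)) > 1e-8) {
    abort(sprintf("`%s` must have unit diagonal.", what))
  }
  if (max(abs(x)) > 1 + 1e-8) {
    abort(sprintf("`%s` entries must lie in [-1, 1].", what))
  }
  invisible(TRUE)
}

# Derives a stream of sub-seeds from one master seed, staying inside the
# 32-bit integer range R requires.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
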