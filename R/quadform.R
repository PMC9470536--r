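# Tail probabilities for quadratic forms in normal variables:
# Q = sum_i lambda_i * chisq_1. The sQTL statistic T = sum z^2 with
# z ~ MVN(0, R) follows this law with lambda = eigenvalues of R.

P_FLOOR <- 1e-320  # output clamp; avoids underflow to exactly 0 in TSVs

# cumulant generating function and derivatives, valid Re(z) < 1/(2 max lambda)
wchisq_cgf <- function(z, lambda) -0.5 * sum(log(1 - 2 * z * lambda))
wchisq_cgf_d1 <- function(z, lambda) sum(lambda / (1 - 2 * z * lambda))
wchisq_cgf_d2 <- function(z, lambda) sum(2 * lambda^2 / (1 - 2 * z * lambda)^2)

# Solves K'(s) = x for the saddlepoint; K' is increasing on (-Inf, 1/(2*lmax)).
wchisq_saddle <- function(x, lambda) {
  lmax <- max(lambda)
  if (x >= sum(lambda)) {
    upper <- (1 - 1e-12) / (2 * lmax)
    lower <- 0
  } else {
    lower <- -1 / (2 * lmax)
    while (wchisq_cgf_d1(lower, lambda) > x) lower <- lower * 2
    upper <- 0
  }
  uniroot(function(s) wchisq_cgf_d1(s, lambda) - x,
          lower = lower, upper = upper, tol = 1e-14,
          extendInt = "no")$root
}

all_equal_lambda <- function(lambda) {
  diff(range(lambda)) <= 1e-12 * max(lambda)
}

#' Saddlepoint tail probability for a weighted sum of chi-squares
#'
#' Upper-tail probability of `sum(lambda_i * chisq_1)` at `q` via the
#' Lugannani-Rice saddlepoint formula (Kuonen's form for quadratic forms in
#' normals). When all weights are equal the chi-square closed form is exact
#' and is used directly; near the distribution mean, where the saddlepoint
#' formula degenerates, the characteristic-function inversion of
#' [pvalue_davies()] is used instead.
#'
#' @param q Observed statistic (scalar, >= 0).
#' @param lambda Non-negative eigenvalue weights, at least one positive.
#' @return Tail probability in (0, 1].
#' @seealso [pvalue_davies()], [pvalue_montecarlo()]
#' @examples
#' pvalue_saddlepoint(3.84, 1)          # ~0.05, chi-square(1)
#' pvalue_saddlepoint(10, c(2, 1, 0.5))
#' @export
pvalue_saddlepoint <- function(q, lambda) {
  lambda <- check_lambda(lambda)
  if (q <= 0) return(1)
  if (all_equal_lambda(lambda)) {
    return(clamp_p(pchisq(q / lambda[1], df = length(lambda),
                          lower.tail = FALSE)))
  }
  s <- tryCatch(wchisq_saddle(q, lambda), error = function(e) NA_real_)
  if (!is.finite(s)) return(pvalue_davies(q, lambda))
  w <- sign(s) * sqrt(max(0, 2 * (s * q - wchisq_cgf(s, lambda))))
  v <- s * sqrt(wchisq_cgf_d2(s, lambda))
  if (abs(w) < 1e-4 || v == 0) {
    # the Lugannani-Rice correction is 0/0 at the mean; inversion is stable
    return(pvalue_davies(q, lambda))
  }
  clamp_p(pnorm(w + log(v / w) / w, lower.tail = FALSE))
}

#' Tail probability by numerical inversion of the characteristic function
#'
#' Computes the upper-tail probability of `sum(lambda_i * chisq_1)` by
#' numerically inverting the characteristic function, the same inversion
#' family as Davies' algorithm. Below the mean the standard Imhof-form
#' integral is used; above the mean the inversion contour is shifted to the
#' saddlepoint abscissa (an exponentially tilted integrand), which preserves
#' relative accuracy deep in the tail where the untilted integral would lose
#' the result to cancellation.
#'
#' @inheritParams pvalue_saddlepoint
#' @param acc Requested accuracy (relative, for the integral). If the
#'   quadrature cannot certify it, the achieved estimate is attached as
#'   attribute `"accuracy"` with a warning.
#' @return Tail probability in (0, 1], with attribute `"accuracy"`.
#' @examples
#' pvalue_davies(7, c(3, 1))
#' @export
pvalue_davies <- function(q, lambda, acc = 1e-12) {
  lambda <- check_lambda(lambda)
  if (q <= 0) {
    return(structure(1, accuracy = 0))
  }
  if (all_equal_lambda(lambda)) {
    p <- clamp_p(pchisq(q / lambda[1], df = length(lambda),
                        lower.tail = FALSE))
    return(structure(p, accuracy = 0))
  }
  mu <- sum(lambda)
  res <- if (q <= mu) {
    imhof_integral(q, lambda, acc)
  } else {
    tilted_inversion(q, lambda, acc)
  }
  p <- clamp_p(res$p)
  if (res$rel_err > max(acc * 10, 1e-3)) {
    warn(sprintf(
      "characteristic-function inversion reached relative accuracy %.2e (requested %.2e)",
      res$rel_err, acc))
  }
  structure(p, accuracy = res$rel_err)
}

# Imhof (1961) form: P(Q > x) = 1/2 + (1/pi) * int_0^inf sin(theta(u))/(u rho(u)) du
imhof_integral <- function(x, lambda, acc) {
  f <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - x * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(th) / (u * rho)
    out[u == 0] <- (sum(lambda) - x) / 2
    out
  }
  it <- robust_integrate(f)
  p <- 0.5 + it$value / pi
  list(p = p, rel_err = (it$abs.error / pi) / max(p, .Machine$double.xmin))
}

# Inversion along Re(z) = s (the saddlepoint): no cancellation for small p.
# P(Q > x) = (1/pi) * int_0^inf Re[ exp(K(s+it) - (s+it) x) / (s+it) ] dt
tilted_inversion <- function(x, lambda, acc) {
  s <- wchisq_saddle(x, lambda)
  lmax <- max(lambda)
  s <- min(max(s, 1e-8 / (2 * lmax)), (1 - 1e-9) / (2 * lmax))
  a0 <- wchisq_cgf(s, lambda) - s * x  # log of the integrand scale
  f <- function(t) {
    z <- complex(real = s, imaginary = t)
    kz <- vapply(z, function(zz) -0.5 * sum(log(1 - 2 * zz * lambda)),
                 complex(1))
    Re(exp(kz - z * x - a0) / z)
  }
  it <- robust_integrate(f)
  p <- exp(a0 + log(max(it$value, .Machine$double.xmin))) / pi
  if (it$value <= 0) p <- 0
  list(p = p, rel_err = it$abs.error / max(it$value, .Machine$double.xmin))
}

robust_integrate <- function(f) {
  for (rt in c(1e-11, 1e-9, 1e-7)) {
    it <- tryCatch(
      integrate(f, 0, Inf, rel.tol = rt, abs.tol = 0, subdivisions = 500L,
                stop.on.error = FALSE),
      error = function(e) NULL)
    if (!is.null(it) && it$message %in% c("OK", "roundoff error was detected")) {
      return(it)
    }
  }
  if (is.null(it)) abort("characteristic-function inversion failed")
  it
}

#' Monte Carlo tail probability for the heterogeneity statistic
#'
#' Simulates `z ~ MVN(0, R)` and estimates `P(sum z^2 >= q)` with the
#' add-one estimator `(1 + #exceedances) / (n_draws + 1)`. Serves as a
#' model-free oracle for the analytic tail approximations.
#'
#' @param q Observed statistic.
#' @param R Correlation matrix of the standardized differences.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer seed; the draw is reproducible.
#' @return A list with elements `p` and `mc_se` (binomial standard error).
#' @export
pvalue_montecarlo <- function(q, R, n_draws = 1e5, seed = 1L) {
  check_correlation_matrix(R, "R")
  if (q <= 0) return(list(p = 1, mc_se = 0))
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  set.seed(seed)
  draws <- matrix(rnorm(n_draws * length(lam))^2, ncol = length(lam))
  tsim <- drop(draws %*% lam)
  p <- (1 + sum(tsim >= q)) / (n_draws + 1)
  list(p = p, mc_se = sqrt(p * (1 - p) / n_draws))
}

check_lambda <- function(lambda) {
  lambda <- as.numeric(lambda)
  if (length(lambda) == 0 || any(!is.finite(lambda)) || any(lambda < 0) ||
      max(lambda) <= 0) {
    abort("`lambda` must be non-negative weights with at least one positive.")
  }
  lambda[lambda > 0]
}

clamp_p <- function(p) min(max(p, P_FLOOR), 1)
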