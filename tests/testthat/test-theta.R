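# Error-correlation estimation between isoform-eQTL effects.

test_that("overlap-based theta follows r_p * rho", {
  s <- paste0("S", 1:40)
  set.seed(2)
  a <- setNames(rnorm(40), s)

  # identical sample sets, perfectly anti-correlated abundances
  full <- theta_from_overlap(a, -a)
  expect_equal(full$rho, 1)
  expect_equal(full$theta, -1)

  # disjoint samples: rho = 0, theta = 0
  b <- setNames(rnorm(40), paste0("T", 1:40))
  disj <- theta_from_overlap(a, b)
  expect_equal(disj$n_s, 0L)
  expect_equal(disj$theta, 0)

  # half overlap of equal-size sets: rho = 1/2, theta = r_p / 2
  k <- setNames(rnorm(40), paste0("S", 21:60))
  half <- theta_from_overlap(a, k)
  expect_equal(half$rho, 0.5)
  expect_equal(half$theta, half$r_p * 0.5)

  tiny <- setNames(rnorm(2), paste0("S", 1:2))
  expect_error(theta_from_overlap(tiny, tiny), "3 overlapping")
})

test_that("null-SNP theta recovers a known error correlation", {
  set.seed(55)
  m <- 3
  se <- c(0.1, 0.12, 0.09)
  th_true <- matrix(0.5, m, m)
  diag(th_true) <- 1
  B <- simulate_null_effects(5000, se, th_true)
  tab <- tibble::tibble(
    snp_id = rep(paste0("s", 1:5000), m),
    isoform_id = rep(paste0("iso", 1:m), each = 5000),
    b = c(B),
    p = pchisq((c(B) / rep(se, each = 5000))^2, 1, lower.tail = FALSE))
  tab <- dplyr::filter(tab, TRUE)
  est <- theta_from_null_snps(tab)
  off <- est[upper.tri(est)]
  expect_true(all(abs(off - 0.5) < 0.05))
  expect_equal(diag(est), rep(1, m), ignore_attr = TRUE)
})

test_that("independent errors give theta near zero within the Fisher bound", {
  set.seed(56)
  n_snp <- 4000
  B <- simulate_null_effects(n_snp, c(1, 1), diag(2))
  tab <- tibble::tibble(
    snp_id = rep(paste0("s", 1:n_snp), 2),
    isoform_id = rep(c("i1", "i2"), each = n_snp),
    b = c(B),
    p = pchisq(c(B)^2, 1, lower.tail = FALSE))
  est <- theta_from_null_snps(tab)
  expect_lt(abs(est[1, 2]), 3 / sqrt(n_snp))
})

test_that("insufficient null SNPs for a pair is an error naming the pair", {
  tab <- tibble::tibble(snp_id = rep(paste0("s", 1:10), 2),
                        isoform_id = rep(c("i1", "i2"), each = 10),
                        b = rnorm(20), p = runif(20))
  expect_error(theta_from_null_snps(tab), "i1, i2")
})

test_that("overlap and null-SNP estimates agree on simulated data", {
  set.seed(60)
  n <- 400
  m <- 3
  rc <- 0.6
  R <- matrix(rc, m, m); diag(R) <- 1
  Y <- MASS::mvrnorm(n, rep(0, m), R)
  rownames(Y) <- paste0("S", 1:n)
  # overlap route: full overlap, theta ~ cor(Y)
  th_overlap <- theta_from_overlap(setNames(Y[, 1], rownames(Y)),
                                   setNames(Y[, 2], rownames(Y)))$theta
  # null-SNP route: regress each isoform on many independent null SNPs
  n_snp <- 800
  X <- matrix(rbinom(n * n_snp, 2, 0.3), n, n_snp)
  rows <- lapply(seq_len(n_snp), function(s) {
    f <- lapply(1:m, function(j) fit_isoform_eqtl(X[, s], Y[, j]))
    tibble::tibble(snp_id = paste0("s", s),
                   isoform_id = paste0("i", 1:m),
                   b = vapply(f, `[[`, numeric(1), "b"),
                   p = vapply(f, `[[`, numeric(1), "p"))
  })
  est <- theta_from_null_snps(dplyr::bind_rows(rows))
  expect_lt(abs(est[1, 2] - th_overlap), 0.1)
})

test_that("nearest-correlation repair clips negative eigenvalues", {
  x <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(x)$values), 0)
  y <- nearest_correlation(x)
  expect_gte(min(eigen(y)$values), -1e-10)
  expect_equal(diag(y), rep(1, 3))
  # already-valid input is untouched
  z <- random_correlation(4)
  expect_equal(nearest_correlation(z), z)
})
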