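# The heterogeneity test: pairwise differences, standardization, the
# statistic, and its invariances.

test_that("pairwise differences and covariance follow the four-term expansion", {
  # m = 2, equal effects: zero difference
  d2 <- pairwise_differences(c(1, 1), c(1, 1), diag(2))
  expect_equal(d2$d, 0)
  expect_equal(drop(d2$V), 2)  # independent unit SEs

  # m = 3, independent errors, unit SEs: hand-derived V for pairs (12),(13),(23)
  d3 <- pairwise_differences(c(0.3, -0.1, 0.2), rep(1, 3), diag(3))
  V_hand <- matrix(c(2, 1, -1,
                     1, 2, 1,
                     -1, 1, 2), 3, 3, byrow = TRUE)
  expect_equal(d3$V, V_hand)
  expect_equal(d3$d, c(0.4, 0.1, -0.3))

  # diagonal honours the error correlation
  th <- matrix(c(1, 0.6, 0.6, 1), 2)
  dd <- pairwise_differences(c(0, 1), c(2, 3), th)
  expect_equal(drop(dd$V), 4 + 9 - 2 * 0.6 * 6)
})

test_that("pairwise differences against a brute-force covariance oracle", {
  set.seed(5)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    th <- random_correlation(m)
    se <- runif(m, 0.5, 2)
    b <- rnorm(m)
    dv <- pairwise_differences(b, se, th)
    # oracle: explicit four-term expansion, element by element
    Sb <- th * tcrossprod(se)
    pr <- subset(expand.grid(k = 1:m, j = 1:m), j < k)
    pr <- pr[order(pr$j, pr$k), ]
    q <- nrow(pr)
    V <- matrix(NA_real_, q, q)
    for (a in 1:q) for (bb in 1:q) {
      j <- pr$j[a]; k <- pr$k[a]; g <- pr$j[bb]; h <- pr$k[bb]
      V[a, bb] <- Sb[j, g] - Sb[j, h] - Sb[k, g] + Sb[k, h]
    }
    expect_equal(dv$V, V, tolerance = 1e-12)
  }
})

test_that("standardization yields the documented eigenvalue structure", {
  d1 <- pairwise_differences(c(1, 0), c(1, 1), diag(2))
  s1 <- standardize_differences(d1)
  expect_equal(s1$R, matrix(1, 1, 1))
  expect_equal(s1$lambda, 1)

  d3 <- pairwise_differences(c(0.2, 0, -0.2), rep(1, 3), diag(3))
  s3 <- standardize_differences(d3)
  R_hand <- matrix(c(1, .5, -.5, .5, 1, .5, -.5, .5, 1), 3)
  expect_equal(s3$R, R_hand)
  expect_equal(sort(s3$lambda), c(1.5, 1.5))  # zero mode discarded
  expect_lte(length(s3$lambda), d3$m - 1)
  expect_lte(sum(s3$lambda), 3 + 1e-10)  # trace bound
})

test_that("the statistic is the plain sum of squared standardized differences", {
  d <- pairwise_differences(c(1, -1), c(0.5, 0.5), diag(2))
  s <- standardize_differences(d)
  expect_equal(thistle_statistic(s), sum(s$z^2))
  expect_equal(s$z, 2 / sqrt(0.5))
})

test_that("equal isoform effects give T = 0 and p = 1", {
  r <- thistle_test(rep(0.7, 4), runif(4, 0.1, 1), diag(4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("m = 2 with independent errors reduces to the z-difference test", {
  set.seed(31)
  for (i in 1:100) {
    b <- rnorm(2)
    se <- runif(2, 0.2, 2)
    r <- thistle_test(b, se, diag(2))
    z2 <- (b[1] - b[2])^2 / (se[1]^2 + se[2]^2)
    expect_equal(r$p, pchisq(z2, 1, lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("the test is invariant to common scaling and to isoform order", {
  set.seed(77)
  m <- 4
  th <- random_correlation(m)
  b <- rnorm(m)
  se <- runif(m, 0.3, 1)
  r0 <- thistle_test(b, se, th)
  r_scaled <- thistle_test(10 * b, 10 * se, th)
  expect_equal(r_scaled$statistic, r0$statistic, tolerance = 1e-10)
  expect_equal(r_scaled$p, r0$p, tolerance = 1e-10)
  perm <- sample(m)
  r_perm <- thistle_test(b[perm], se[perm], th[perm, perm])
  expect_equal(r_perm$statistic, r0$statistic, tolerance = 1e-10)
  expect_equal(r_perm$p, r0$p, tolerance = 1e-8)
})

test_that("isoforms with missing estimates are dropped, with a sentinel below m = 2", {
  th <- diag(3)
  r <- thistle_test(c(1, NA, 0), c(0.5, 0.4, 0.5), th)
  expect_equal(r$m, 2L)
  expect_true(is.finite(r$p))
  r2 <- thistle_test(c(1, NA, NA), c(0.5, 0.4, 0.5), th)
  expect_true(is.na(r2$p))
  expect_equal(r2$reason, "fewer_than_2_isoforms")
})

test_that("null p-values are uniform when effects are drawn from their error law", {
  set.seed(123)
  m <- 3
  se <- c(0.8, 1, 1.2)
  th <- matrix(0.5, m, m); diag(th) <- 1
  B <- simulate_null_effects(10000, se, th)
  p <- vapply(seq_len(nrow(B)), function(i) {
    thistle_test(B[i, ], se, th)$p
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("p decreases monotonically with heterogeneity magnitude", {
  se <- rep(0.1, 3)
  th <- diag(3)
  contr <- c(1, 0, -1)
  p <- vapply(c(0.05, 0.1, 0.2, 0.4), function(es) {
    thistle_test(es * contr, se, th)$p
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})
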