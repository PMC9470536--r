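# Expression filtering, normalization, transformation, SNP QC.

test_that("low-expression filter uses the strict 'more than' rule", {
  v <- matrix(1, 10, 3)
  v[1:9, 1] <- 0.05   # below 0.1 in 90% of samples -> dropped
  v[1:8, 2] <- 0.05   # exactly 80%: kept
  colnames(v) <- c("a", "b", "c")
  ab <- toy_abundance(v)
  out <- filter_low_expression(ab, min_isoforms = 1)
  expect_setequal(out$features$feature_id, c("b", "c"))

  allz <- toy_abundance(cbind(a = rep(0, 10), b = rep(1, 10)))
  out2 <- filter_low_expression(allz, min_isoforms = 1)
  expect_equal(out2$features$feature_id, "b")

  expect_error(filter_low_expression(toy_abundance(cbind(a = rep(0, 5),
                                                         b = rep(0, 5))),
                                     min_isoforms = 1),
               "threshold")
})

test_that("genes left with a single isoform are dropped with a message", {
  v <- cbind(g1.a = rep(1, 10), g1.b = c(rep(0, 9), 1), g2.a = rep(1, 10),
             g2.b = rep(1, 10))
  rownames(v) <- paste0("S", 1:10)
  ab <- abundance_matrix(v, tibble::tibble(
    feature_id = colnames(v), gene_id = rep(c("g1", "g2"), each = 2)),
    level = "isoform")
  expect_message(out <- filter_low_expression(ab), "dropping 1 gene")
  expect_setequal(unique(out$features$gene_id), "g2")
  expect_equal(attr(out, "dropped_genes"), "g1")
})

test_that("quantile normalization equalizes sorted values across samples", {
  ab <- toy_abundance(rbind(c(1, 2, 3), c(4, 5, 6)))
  out <- quantile_normalize(ab)
  expect_equal(unname(out$values[1, ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[2, ]), c(2.5, 3.5, 4.5))

  same <- toy_abundance(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(quantile_normalize(same)$values, same$values)

  tied <- toy_abundance(rbind(c(1, 1, 2), c(3, 4, 5)))
  out2 <- quantile_normalize(tied)
  expect_equal(out2$values[1, 1], out2$values[1, 2])

  set.seed(4)
  r <- toy_abundance(matrix(rexp(60), 6, 10))
  outr <- quantile_normalize(r)
  sorted <- apply(outr$values, 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("rank-based inverse normal transform follows the Blom convention", {
  x <- c(3, 1, 2)
  out <- rank_inverse_normal(x)
  expect_equal(out, qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4)))
  expect_equal(out[3], 0)  # middle value maps to the median

  # invariance under strictly monotone transforms
  y <- sort(rexp(15))
  expect_equal(rank_inverse_normal(y), rank_inverse_normal(seq_along(y)))
  expect_equal(rank_inverse_normal(exp(y)), rank_inverse_normal(y))

  # ties share the average rank, hence identical output
  z <- rank_inverse_normal(c(5, 5, 1, 9))
  expect_equal(z[1], z[2])
  expect_equal(z[1], qnorm((2.5 - 3 / 8) / 4.25))

  expect_error(rank_inverse_normal(rep(2, 5)), "identical")
  expect_error(rank_inverse_normal(3), "2 finite")
})

test_that("residualization is orthogonal, exact and idempotent", {
  set.seed(21)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(rnorm(n * 4), n, 4)
  Y[, 1] <- 2 * X[, 1] - X[, 2]  # exactly linear in covariates
  ab <- toy_abundance(Y)
  out <- residualize(ab, X)
  expect_lt(max(abs(out$values[, 1])), 1e-10)
  expect_lt(max(abs(crossprod(X, out$values))), 1e-10)
  expect_lt(max(abs(colSums(out$values))), 1e-10)
  twice <- residualize(out, X)
  expect_equal(twice$values, out$values, tolerance = 1e-10)

  # constant covariate alone: mean-centring
  cent <- residualize(ab, matrix(5, n, 1))
  expect_equal(cent$values, sweep(Y, 2, colMeans(Y)),
               ignore_attr = TRUE)

  expect_error(residualize(ab, cbind(X, X[, 1])), "collinear")
})

test_that("SNP QC removes low-MAF, low-call-rate and monomorphic variants", {
  set.seed(8)
  n <- 200
  good <- rbinom(n, 2, 0.3)
  low_maf <- rbinom(n, 2, 0.005)
  missing10 <- good
  missing10[1:20] <- NA
  mono <- rep(0, n)
  dos <- cbind(good = good, low_maf = low_maf, missing10 = missing10,
               mono = mono)
  rownames(dos) <- paste0("S", 1:n)
  g <- genotype_matrix(dos)
  out <- snp_qc(g)
  expect_equal(out$snps$snp_id, "good")
  counts <- attr(out, "qc_counts")
  expect_gte(counts[["maf"]], 2)       # low_maf and mono both fail MAF
  expect_equal(counts[["call_rate"]], 1)
})

test_that("the Hardy-Weinberg exact test matches hand enumeration", {
  # n = 2, one het vs one each hom: conditional P(h=0) = 1/3
  expect_equal(hwe_exact_test(0, 1, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(2, 0, 0), 1, tolerance = 1e-12)
  # monomorphic: always 1
  expect_equal(hwe_exact_test(0, 50, 0), 1)
  # extreme disequilibrium is detected
  expect_lt(hwe_exact_test(0, 50, 50), 1e-6)
  # equilibrium-looking data is not
  expect_gt(hwe_exact_test(50, 25, 25), 0.5)
})
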