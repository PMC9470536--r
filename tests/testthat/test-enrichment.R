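# Annotation membership, matched-control sampling, fold enrichment.

test_that("BED half-open membership at 1-based SNP positions", {
  snps <- tibble::tibble(snp_id = c("a", "b"), chrom = "1",
                         pos = c(100L, 101L))
  track <- tibble::tibble(chrom = "1", start = 99L, end = 100L)
  out <- annotate_snps(snps, list(cat = track))
  expect_true(out$cat[out$snp_id == "a"])    # 0-based 99 is 1-based 100
  expect_false(out$cat[out$snp_id == "b"])

  # overlapping intervals count once
  track2 <- tibble::tibble(chrom = "1", start = c(90L, 95L),
                           end = c(105L, 102L))
  out2 <- annotate_snps(snps, list(cat = track2))
  expect_true(all(out2$cat))
  expect_type(out2$cat, "logical")
})

test_that("control sampling matches the query stratum histogram exactly", {
  pool <- simulate_snp_pool(5000, prevalence = c(x = 0.1), seed = 3)
  set.seed(4)
  query <- pool[sample.int(5000, 200), ]
  sets <- sample_controls(query, pool, n_sets = 20, seed = 9)
  expect_true(all(lengths(sets) == 200))
  strata <- thistle:::matching_strata(pool)
  q_hist <- table(thistle:::stratum_of(query, strata))
  for (s in sets[1:5]) {
    c_hist <- table(thistle:::stratum_of(pool[s, ], strata))
    expect_equal(c_hist[names(q_hist)], q_hist, ignore_attr = TRUE)
    expect_false(any(pool$snp_id[s] %in% query$snp_id))
  }
  sets2 <- sample_controls(query, pool, n_sets = 20, seed = 9)
  expect_identical(sets, sets2)
})

test_that("a pool equal to the query has no eligible controls", {
  pool <- simulate_snp_pool(100, seed = 5)
  expect_error(sample_controls(pool, pool, n_sets = 5), "coarsen")
})

test_that("fold enrichment is linear in the query prevalence", {
  pool <- simulate_snp_pool(20000, prevalence = c(cat = 0.2), seed = 11)
  query <- pool[sample.int(20000, 400), ]
  sets <- sample_controls(query, pool, n_sets = 150, seed = 2)
  base <- fold_enrichment(query, pool, sets, "cat")
  doubled <- query
  doubled$cat <- rep(c(TRUE, FALSE), length.out = 400)[order(!query$cat)]
  # construct a query with exactly twice the membership count
  doubled$cat <- seq_len(400) %in% seq_len(2 * sum(query$cat))
  d2 <- fold_enrichment(doubled, pool, sets, "cat")
  expect_equal(d2$fold / base$fold,
               mean(doubled$cat) / mean(query$cat), tolerance = 1e-10)
  expect_true(base$ci_low <= base$fold && base$fold <= base$ci_high)
})

test_that("an empty control category yields an undefined fold with counts", {
  pool <- simulate_snp_pool(2000, prevalence = c(never = 0), seed = 7)
  query <- pool[1:50, ]
  query$never <- TRUE
  sets <- sample_controls(query, pool, n_sets = 100, seed = 1)
  out <- fold_enrichment(query, pool, sets, "never")
  expect_true(is.na(out$fold))
  expect_equal(out$p_query, 1)
  expect_equal(out$p_control, 0)
})

test_that("fold estimates are invariant to row and set ordering", {
  pool <- simulate_snp_pool(5000, prevalence = c(cat = 0.15), seed = 21)
  query <- pool[sample.int(5000, 150), ]
  sets <- sample_controls(query, pool, n_sets = 100, seed = 3)
  a <- fold_enrichment(query, pool, sets, "cat")
  b <- fold_enrichment(query[sample.int(150), ], pool, rev(sets), "cat")
  expect_equal(a$fold, b$fold)
  expect_equal(a$se, b$se)
})

test_that("the report wrapper covers all logical categories", {
  pool <- simulate_snp_pool(4000, prevalence = c(c1 = 0.1, c2 = 0.3),
                            seed = 2)
  query <- pool[sample.int(4000, 100), ]
  rep <- enrichment_report(query, pool, n_sets = 100, seed = 5)
  expect_setequal(rep$category, c("c1", "c2"))
  expect_s3_class(rep, "enrichment_report")
  g <- glance(rep)
  expect_equal(g$n_categories, 2L)
})
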