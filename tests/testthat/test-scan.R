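# Pipeline-level scans, tidiers and plots.

make_scan_fixture <- function(n = 150, n_snps = 8, seed = 301) {
  seeds <- thistle:::derive_seeds(seed, 2)
  g <- simulate_genotypes(n, 0.3, n_snps = n_snps, seed = seeds[1])
  cfg <- sim_config(n = n, m = 3, scenario = "sqtl", effect_size = 0.35)
  sim <- simulate_abundance(g, cfg, seed = seeds[2], causal = 2L)
  gm <- tibble::tibble(gene_id = "gene1", chrom = "1", start = 1L,
                       end = 10000L, strand = "+", tss = 1L)
  list(g = g, sim = sim, gm = gm)
}

test_that("individual-level scan finds the causal variant and is tidy-able", {
  fx <- make_scan_fixture()
  res <- thistle_scan(fx$g, fx$sim$abundance, fx$gm,
                      keep_isoform_eqtl = TRUE)
  expect_s3_class(res, "thistle_scan")
  expect_equal(nrow(res), 8)
  lead <- res$snp_id[which.min(res$p)]
  expect_equal(lead, fx$sim$truth$causal_snp[1])

  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "thistle_scan"))
  gl <- glance(res)
  expect_equal(gl$n_genes, 1L)
  expect_equal(gl$n_tests, 8L)

  p1 <- autoplot(res)
  expect_s3_class(p1, "ggplot")
  eq <- attr(res, "isoform_eqtl")
  p2 <- plot_isoform_effects(eq, lead)
  expect_s3_class(p2, "ggplot")
})

test_that("summary-level path approximates the individual-level path", {
  fx <- make_scan_fixture(n = 300, n_snps = 60, seed = 88)
  ind <- thistle_scan(fx$g, fx$sim$abundance, fx$gm,
                      keep_isoform_eqtl = TRUE)
  summ <- thistle_from_summary(attr(ind, "isoform_eqtl"), min_null = 20)
  merged <- dplyr::inner_join(tidy(ind), tidy(summ),
                              by = c("gene_id", "snp_id"))
  expect_equal(nrow(merged), 60)
  expect_gt(cor(merged$p.x, merged$p.y, method = "spearman"), 0.95)
})

test_that("a supplied theta short-circuits the null-SNP estimator", {
  fx <- make_scan_fixture(n = 120, n_snps = 4, seed = 7)
  ind <- thistle_scan(fx$g, fx$sim$abundance, fx$gm,
                      keep_isoform_eqtl = TRUE)
  eq <- attr(ind, "isoform_eqtl")
  iso <- sort(unique(eq$isoform_id))
  th <- diag(3)
  dimnames(th) <- list(iso, iso)
  out <- thistle_from_summary(eq, theta = list(gene1 = th))
  expect_equal(nrow(out), 4)
  expect_true(all(is.finite(out$p)))
})

test_that("the CLI round-trips simulate -> preprocess -> scan via files", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "sim")
  thistle_cli(c("simulate", "--n", "120", "--m", "3", "--scenario", "sqtl",
                "--effect-size", "0.5", "--n-snps", "4", "--seed", "5",
                "--out-prefix", prefix))
  expect_true(file.exists(paste0(prefix, ".abundance.tsv")))
  gm_path <- file.path(dir, "gene_models.tsv")
  readr::write_tsv(tibble::tibble(gene_id = "gene1", chrom = "1",
                                  start = 1L, end = 10000L, strand = "+",
                                  tss = 1L), gm_path)
  out_path <- file.path(dir, "res.tsv")
  thistle_cli(c("thistle", "--mode", "individual",
                "--genotypes", paste0(prefix, ".genotypes.tsv"),
                "--snp-info", paste0(prefix, ".snps.tsv"),
                "--abundance", paste0(prefix, ".abundance.tsv"),
                "--gene-map", paste0(prefix, ".gene_map.tsv"),
                "--gene-models", gm_path, "--out", out_path))
  res <- read_results(out_path)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_error(thistle_cli(c("nonsense")), "unknown subcommand")
})
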