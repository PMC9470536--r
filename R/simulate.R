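# Abundance-level simulation bench: genotypes from Hardy-Weinberg binomial
# draws; isoform abundances from a multivariate normal model or from
# (over)dispersed counts converted to TPM-like proportions. Scenarios
# separate overall-expression effects (eQTL) from heterogeneous per-isoform
# effects (sQTL).

#' Simulation configuration
#'
#' @param n Sample count (>= 10).
#' @param m Isoforms per gene (>= 2).
#' @param maf Causal-variant allele frequency in (0, 0.5].
#' @param scenario `"null"`, `"eqtl_only"` (equal per-isoform effects),
#'   `"sqtl"` (zero-sum heterogeneous effects: no net expression effect)
#'   or `"sqtl_plus_eqtl"` (heterogeneous effects with nonzero mean).
#' @param effect_size Scalar heterogeneity magnitude: the per-isoform
#'   effects are `effect_size` times a fixed zero-sum contrast with unit
#'   root-mean-square (residual-SD units in `mvn` mode, log-abundance
#'   units in `counts` mode). Alternatively a full length-`m` effect
#'   vector.
#' @param eqtl_effect Shared effect added to every isoform in the
#'   `eqtl_only` and `sqtl_plus_eqtl` scenarios (defaults to
#'   `effect_size`).
#' @param dispersion Overdispersion of the count model (0 = Poisson;
#'   otherwise negative binomial with size `1/dispersion`).
#' @param residual_corr Residual correlation between isoforms (common
#'   off-diagonal of the residual covariance; on the log scale in
#'   `counts` mode).
#' @param distribution `"mvn"` or `"counts"`.
#' @param sigma_log Log-scale residual SD for `counts` mode.
#' @param lib_size Library-size constant for the counts-to-abundance
#'   conversion.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 300, m = 3, maf = 0.3,
                       scenario = c("null", "eqtl_only", "sqtl",
                                    "sqtl_plus_eqtl"),
                       effect_size = 0.2, eqtl_effect = NULL,
                       dispersion = 0, residual_corr = 0.5,
                       distribution = c("mvn", "counts"),
                       sigma_log = 0.5, lib_size = 1e6) {
  scenario <- match.arg(scenario)
  distribution <- match.arg(distribution)
  stopifnot(n >= 10, m >= 2, maf > 0, maf <= 0.5, dispersion >= 0,
            residual_corr > -1 / (m - 1), residual_corr < 1)
  structure(list(n = n, m = m, maf = maf, scenario = scenario,
                 effect_size = effect_size,
                 eqtl_effect = eqtl_effect %||%
                   (if (is.numeric(effect_size) && length(effect_size) == 1)
                      effect_size else 0),
                 dispersion = dispersion, residual_corr = residual_corr,
                 distribution = distribution, sigma_log = sigma_log,
                 lib_size = lib_size),
            class = "sim_config")
}

# Zero-sum contrast with unit root-mean-square, fixed across runs.
sqtl_contrast <- function(m) {
  u <- seq(-1, 1, length.out = m)
  u <- u - mean(u)
  u / sqrt(mean(u^2))
}

# Per-isoform true effects implied by a scenario.
true_effects <- function(cfg) {
  if (length(cfg$effect_size) == cfg$m) return(as.numeric(cfg$effect_size))
  if (length(cfg$effect_size) != 1) {
    abort("`effect_size` must be scalar or length m.")
  }
  switch(cfg$scenario,
    null = rep(0, cfg$m),
    eqtl_only = rep(cfg$eqtl_effect, cfg$m),
    sqtl = cfg$effect_size * sqtl_contrast(cfg$m),
    sqtl_plus_eqtl = cfg$effect_size * sqtl_contrast(cfg$m) +
      cfg$eqtl_effect)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are Binomial(2, maf) draws, independent across SNPs.
#'
#' @param n Sample count.
#' @param maf Allele frequency in (0, 0.5].
#' @param n_snps Number of SNPs.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with samples `S1..Sn`, SNPs `snp1..`.
#' @export
simulate_genotypes <- function(n, maf, n_snps = 1, seed = 1L) {
  stopifnot(maf > 0, maf <= 0.5)
  if (2 * n * maf < 5) {
    abort("expected minor allele count below 5; increase n or maf.")
  }
  set.seed(seed)
  dos <- matrix(rbinom(n * n_snps, 2, maf), n, n_snps,
                dimnames = list(paste0("S", seq_len(n)),
                                paste0("snp", seq_len(n_snps))))
  genotype_matrix(dos, tibble(snp_id = colnames(dos), chrom = "1",
                              pos = seq_len(n_snps) * 1000L,
                              ref = "A", alt = "G"))
}

#' Simulate isoform abundances for one gene
#'
#' `mvn` mode: per-sample isoform vector `mu0 + beta * dosage + e`,
#' `e ~ MVN(0, Sigma)` with unit variances and common off-diagonal
#' `residual_corr`. `counts` mode: the same linear predictor on the log
#' scale (plus a correlated log-normal residual), drawn as Poisson
#' (`dispersion = 0`) or negative binomial counts and converted to
#' TPM-like values via per-sample proportions times `lib_size`.
#'
#' @param genotypes A [genotype_matrix()]; the causal SNP is column
#'   `causal` (default 1).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param causal Column index of the causal SNP.
#' @param gene_id Identifier used for features.
#' @return List with `abundance` (an [abundance_matrix()]) and `truth`
#'   (tibble: `gene_id`, `scenario`, `causal_snp`, `isoform_id`, `beta`).
#' @export
simulate_abundance <- function(genotypes, cfg, seed = 1L, causal = 1L,
                               gene_id = "gene1") {
  stopifnot(inherits(cfg, "sim_config"))
  x <- genotypes$dosages[, causal]
  n <- length(x)
  m <- cfg$m
  beta <- true_effects(cfg)
  R <- matrix(cfg$residual_corr, m, m)
  diag(R) <- 1
  set.seed(seed)
  E <- matrix(rnorm(n * m), n, m) %*% chol(R)
  iso <- paste0(gene_id, ".iso", seq_len(m))
  if (cfg$distribution == "mvn") {
    mu0 <- runif(m, 5, 50)
    Y <- rep(1, n) %*% t(mu0) + outer(x, beta) + E
  } else {
    mu0 <- runif(m, 20, 200)
    eta <- rep(1, n) %*% t(log(mu0)) + outer(x, beta) + cfg$sigma_log * E
    mu <- exp(eta)
    counts <- if (cfg$dispersion == 0) {
      matrix(rpois(n * m, mu), n, m)
    } else {
      matrix(rnbinom(n * m, mu = mu, size = 1 / cfg$dispersion), n, m)
    }
    tot <- pmax(rowSums(counts), 1)
    Y <- counts / tot * cfg$lib_size
  }
  dimnames(Y) <- list(rownames(genotypes$dosages), iso)
  ab <- abundance_matrix(Y, tibble(feature_id = iso, gene_id = gene_id),
                         level = "isoform")
  truth <- tibble(gene_id = gene_id, scenario = cfg$scenario,
                  causal_snp = colnames(genotypes$dosages)[causal],
                  isoform_id = iso, beta = beta)
  list(abundance = ab, truth = truth)
}

#' Heterogeneity test for one simulated (or real) gene at one variant
#'
#' Individual-level convenience path used by the bench: per-isoform OLS
#' fits of the abundance columns on the dosage, theta from the abundance
#' correlations, then [thistle_test()].
#'
#' @param dosage Dosage vector.
#' @param Y Samples x isoforms abundance matrix, row-aligned with
#'   `dosage`.
#' @param covariates Optional covariate matrix.
#' @inheritParams thistle_test
#' @return One-row tibble as from [thistle_test()].
#' @export
thistle_test_individual <- function(dosage, Y, covariates = NULL,
                                    method = "saddlepoint",
                                    eig_tol = 1e-8) {
  x <- dosage
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  k <- 0L
  if (!is.null(covariates)) {
    qx <- qr(cbind(1, as.matrix(covariates)))
    x <- qr.resid(qx, x)
    Y <- qr.resid(qx, Y)
    k <- ncol(as.matrix(covariates))
  } else {
    x <- x - mean(x)
    Y <- sweep(Y, 2, colMeans(Y))
  }
  sxx <- sum(x^2)
  if (sxx == 0) {
    return(tibble(gene_id = NA_character_, snp_id = NA_character_,
                  m = ncol(Y), q = NA_integer_, n_lambda = NA_integer_,
                  statistic = NA_real_, p = NA_real_, method = method,
                  reason = "monomorphic"))
  }
  n <- length(x)
  b <- drop(crossprod(x, Y)) / sxx
  sigma2 <- pmax(0, colSums(Y^2) - b^2 * sxx) / (n - k - 2L)
  se <- sqrt(sigma2 / sxx)
  theta <- theta_from_abundance(Y)
  thistle_test(b, se, theta, method = method, eig_tol = eig_tol)
}

#' Run the simulation bench over replicate genes
#'
#' Simulates `n_genes` independent genes under `cfg` (one causal variant
#' each) and runs the full individual-level heterogeneity test on each.
#' Deterministic given `seed`.
#'
#' @param n_genes Number of replicate genes.
#' @param cfg A [sim_config()].
#' @param seed Integer master seed.
#' @param method Tail approximation passed to [thistle_test()].
#' @return Tibble: `gene`, `scenario`, `statistic`, `p`.
#' @export
run_bench <- function(n_genes, cfg, seed = 1L, method = "saddlepoint") {
  seeds <- derive_seeds(seed, 2 * n_genes)
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    geno <- simulate_genotypes(cfg$n, cfg$maf, n_snps = 1,
                               seed = seeds[2 * g - 1])
    if (var(geno$dosages[, 1]) == 0) next  # monomorphic draw; no test
    sim <- simulate_abundance(geno, cfg, seed = seeds[2 * g])
    fit <- thistle_test_individual(geno$dosages[, 1], sim$abundance$values,
                                   method = method)
    rows[[g]] <- tibble(gene = g, scenario = cfg$scenario,
                        statistic = fit$statistic, p = fit$p)
  }
  dplyr::bind_rows(rows)
}
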