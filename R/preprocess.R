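# Expression and genotype preparation: low-expression filtering, per-sample
# quantile normalization, covariate residualization, rank-based inverse
# normal transformation, and SNP quality control.

#' Preprocessing thresholds
#'
#' Defaults follow common cohort RNA-seq QTL practice: isoforms with
#' TPM < 0.1 in more than 80% of samples are removed; SNPs are kept with
#' MAF > 0.01, Hardy-Weinberg exact P > 1e-6 and call rate > 0.95.
#'
#' @param tpm_threshold TPM below which a value counts as unexpressed.
#' @param sample_fraction Fraction of samples; a feature is dropped when it
#'   is unexpressed in strictly more than this fraction.
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test P (exclusive).
#' @param call_rate_min Minimum genotyping call rate (exclusive).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(tpm_threshold = 0.1, sample_fraction = 0.8,
                              maf_min = 0.01, hwe_p_min = 1e-6,
                              call_rate_min = 0.95) {
  stopifnot(tpm_threshold >= 0, sample_fraction > 0, sample_fraction <= 1,
            maf_min >= 0, maf_min < 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            call_rate_min >= 0, call_rate_min <= 1)
  structure(list(tpm_threshold = tpm_threshold,
                 sample_fraction = sample_fraction,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 call_rate_min = call_rate_min),
            class = "preprocess_config")
}

#' Remove lowly expressed isoforms
#'
#' Drops features whose TPM falls below `cfg$tpm_threshold` in strictly
#' more than `cfg$sample_fraction` of the samples. Genes left with fewer
#' than `min_isoforms` isoforms are dropped as well (they cannot enter a
#' splicing heterogeneity test) and reported via a message and the
#' `"dropped_genes"` attribute.
#'
#' @param abundance An [abundance_matrix()] at isoform level, raw TPM.
#' @param cfg A [preprocess_config()].
#' @param min_isoforms Minimum isoforms a gene must retain (default 2);
#'   set to 1 to keep all genes.
#' @return Filtered `abundance_matrix`.
#' @export
filter_low_expression <- function(abundance, cfg = preprocess_config(),
                                  min_isoforms = 2) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  if (min(abundance$values) < 0) abort("TPM values must be non-negative.")
  frac_low <- colMeans(abundance$values < cfg$tpm_threshold)
  keep <- frac_low <= cfg$sample_fraction
  if (!any(keep)) {
    abort("no feature passes the expression filter; review `tpm_threshold`.")
  }
  feats <- abundance$features[keep, ]
  n_iso <- table(feats$gene_id)
  small <- names(n_iso)[n_iso < min_isoforms]
  if (length(small) > 0) {
    inform(sprintf(
      "dropping %d gene(s) left with < %d isoform(s) after filtering",
      length(small), min_isoforms))
    keep_feat <- !(feats$gene_id %in% small)
    feats <- feats[keep_feat, ]
  }
  out <- abundance_matrix(
    abundance$values[, feats$feature_id, drop = FALSE], feats,
    level = abundance$level)
  attr(out, "dropped_genes") <- if (length(small)) small else character(0)
  out
}

#' Quantile-normalize abundances across features within each sample
#'
#' Replaces each sample's values by the rank-indexed reference distribution
#' (the mean of order statistics across samples), so every sample shares an
#' identical sorted value vector afterwards. Ties receive the average of
#' the corresponding reference values.
#'
#' @param abundance An [abundance_matrix()].
#' @return Normalized `abundance_matrix`.
#' @export
quantile_normalize <- function(abundance) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  if (ncol(abundance$values) < 2) abort("need at least 2 features.")
  # limma normalizes columns; our samples are rows
  v <- t(limma::normalizeQuantiles(t(abundance$values), ties = TRUE))
  dimnames(v) <- dimnames(abundance$values)
  abundance_matrix(v, abundance$features, level = abundance$level)
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their (average, for ties) ranks with
#' the Blom offset: `qnorm((rank - 3/8) / (n + 1/4))`. Invariant under any
#' strictly increasing transformation of the input.
#'
#' @param values Numeric vector, length >= 2, finite.
#' @return Transformed vector of the same length.
#' @export
rank_inverse_normal <- function(values) {
  if (length(values) < 2 || any(!is.finite(values))) {
    abort("`values` must be >= 2 finite numbers.")
  }
  if (diff(range(values)) == 0) {
    abort("all values identical; rank transform undefined.")
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Residualize abundances on covariates
#'
#' Replaces each feature by the residuals of an ordinary least-squares fit
#' on the covariates plus an intercept. Residuals are orthogonal to every
#' covariate column; the operation is idempotent.
#'
#' @param abundance An [abundance_matrix()].
#' @param covariates Numeric matrix, samples x k, row-aligned with the
#'   abundance samples. An intercept is always added.
#' @return Residualized `abundance_matrix`.
#' @export
residualize <- function(abundance, covariates) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(abundance$values)) {
    abort("`covariates` rows must align with abundance samples.")
  }
  constant <- apply(covariates, 2, function(v) diff(range(v)) == 0)
  covariates <- covariates[, !constant, drop = FALSE]  # absorbed by intercept
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    abort(paste0("rank-deficient covariates; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qx, abundance$values)
  dimnames(res) <- dimnames(abundance$values)
  abundance_matrix(res, abundance$features, level = abundance$level)
}

#' Apply the rank-based inverse normal transform to every feature
#'
#' Column-wise [rank_inverse_normal()] across samples, the final
#' standardization step before the eQTL regressions.
#'
#' @param abundance An [abundance_matrix()].
#' @return Transformed `abundance_matrix`.
#' @export
rint_features <- function(abundance) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- apply(abundance$values, 2, rank_inverse_normal)
  dimnames(v) <- dimnames(abundance$values)
  abundance_matrix(v, abundance$features, level = abundance$level)
}

#' SNP quality control
#'
#' Removes SNPs failing any of: minor allele frequency > `maf_min`,
#' Hardy-Weinberg exact-test P > `hwe_p_min` (computed on hard-called
#' genotypes, i.e. dosages rounded to 0/1/2), call rate > `call_rate_min`.
#' Per-filter removal counts are reported in the `"qc_counts"` attribute.
#'
#' @param genotypes A [genotype_matrix()]; dosages may contain NA.
#' @param cfg A [preprocess_config()].
#' @return Filtered `genotype_matrix` (possibly with zero SNPs, with a
#'   warning).
#' @export
snp_qc <- function(genotypes, cfg = preprocess_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  call_rate <- colMeans(!is.na(dos))
  maf <- genotypes$snps$maf
  maf[is.na(maf)] <- 0
  hwe_p <- apply(dos, 2, function(d) {
    g <- round(d[!is.na(d)])
    hwe_exact_test(sum(g == 1), sum(g == 0), sum(g == 2))
  })
  fail_cr <- call_rate <= cfg$call_rate_min
  fail_maf <- maf <= cfg$maf_min
  fail_hwe <- hwe_p <= cfg$hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  counts <- c(call_rate = sum(fail_cr), maf = sum(fail_maf),
              hwe = sum(fail_hwe), kept = sum(keep))
  if (!any(keep)) warn("no SNP passes quality control.")
  out <- structure(
    list(dosages = dos[, keep, drop = FALSE],
         snps = genotypes$snps[keep, ]),
    class = "genotype_matrix")
  attr(out, "qc_counts") <- counts
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided (conditional, summed-probability) test for
#' Hardy-Weinberg equilibrium from genotype counts, enumerating the
#' conditional distribution of heterozygote counts given allele counts.
#'
#' @param n_het,n_hom_ref,n_hom_alt Genotype counts.
#' @return P-value in \[0, 1\]; 1 when fewer than 2 informative genotypes.
#' @export
hwe_exact_test <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n < 2) return(1)
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1)
  # conditional probabilities of all possible heterozygote counts
  het_vals <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(het_vals, function(h) {
    rare_hom <- (n_rare - h) / 2
    com_hom <- n - h - rare_hom
    lgamma(n + 1) - lgamma(h + 1) - lgamma(rare_hom + 1) -
      lgamma(com_hom + 1) + h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, het_vals)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}
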