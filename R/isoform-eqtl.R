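# Per-isoform cis-eQTL regression scan. Effects are OLS slopes of
# (preprocessed) isoform abundance on SNP dosage; covariates are projected
# out of both sides first (Frisch-Waugh), which gives the same slope and
# standard error as the joint fit.

#' Map genes to their cis-window SNPs
#'
#' A SNP belongs to a gene's cis window when its position lies within
#' `[start - window, end + window]` (closed boundaries) on the same
#' chromosome. With `anchor = "tss"` the window is centred on the TSS
#' instead of spanning the gene body. Genes with fewer than two isoforms
#' are excluded (no heterogeneity test is possible) and reported.
#'
#' @param gene_models Tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` and either a list-column `isoform_ids` or a column
#'   `n_isoforms`.
#' @param snps Tibble with `snp_id`, `chrom`, `pos` (1-based).
#' @param window Flank size in base pairs (default 2 Mb each side).
#' @param anchor `"gene"` (gene body +/- window) or `"tss"`.
#' @return Named list, gene id -> character vector of SNP ids.
#' @export
build_cis_windows <- function(gene_models, snps, window = 2e6,
                              anchor = c("gene", "tss")) {
  anchor <- match.arg(anchor)
  gene_models <- as_tibble(gene_models)
  snps <- as_tibble(snps)
  if (!any(snps$chrom %in% gene_models$chrom)) {
    abort(paste0("no shared chromosome names; genes use {",
                 paste(unique(gene_models$chrom), collapse = ","),
                 "}, SNPs use {", paste(unique(snps$chrom), collapse = ","),
                 "}"))
  }
  n_iso <- gene_isoform_count(gene_models)
  multi <- n_iso >= 2
  if (any(!multi)) {
    inform(sprintf("excluding %d single-isoform gene(s) from cis mapping",
                   sum(!multi)))
  }
  gm <- gene_models[multi, ]
  lo <- if (anchor == "gene") gm$start else gm$tss
  hi <- if (anchor == "gene") gm$end else gm$tss
  gene_gr <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(pmax(1, lo - window), hi + window))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(gene_gr, snp_gr)
  out <- split(snps$snp_id[S4Vectors::subjectHits(hits)],
               factor(gm$gene_id[S4Vectors::queryHits(hits)],
                      levels = gm$gene_id))
  lapply(out, unname)
}

gene_isoform_count <- function(gene_models) {
  if ("isoform_ids" %in% names(gene_models)) {
    lengths(gene_models$isoform_ids)
  } else if ("n_isoforms" %in% names(gene_models)) {
    gene_models$n_isoforms
  } else {
    abort("gene models need `isoform_ids` or `n_isoforms`.")
  }
}

#' Fit a single isoform-eQTL regression
#'
#' Ordinary least-squares slope of abundance on dosage with covariates and
#' an intercept; the P-value is the chi-square(1) upper tail of
#' `(b/se)^2` (the large-sample one-sided chi-squared test on the squared
#' z-score). Missing dosages are mean-imputed; samples with missing
#' abundance are dropped.
#'
#' @param dosage Numeric dosage vector in \[0, 2\] (NA = missing).
#' @param abundance Numeric abundance vector, aligned with `dosage`.
#' @param covariates Optional numeric matrix of covariates (no intercept).
#' @return One-row tibble `b`, `se`, `p`, `n`, `reason` (`NA` on success;
#'   `"monomorphic"` when the dosage has zero variance).
#' @export
fit_isoform_eqtl <- function(dosage, abundance, covariates = NULL) {
  ok <- is.finite(abundance)
  x <- dosage[ok]
  y <- abundance[ok]
  X <- if (!is.null(covariates)) as.matrix(covariates)[ok, , drop = FALSE]
  k <- if (is.null(X)) 0L else ncol(X)
  n <- length(y)
  if (n < k + 3) abort("too few complete observations.")
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (var(x) == 0) {
    return(tibble(b = NA_real_, se = NA_real_, p = NA_real_, n = n,
                  reason = "monomorphic"))
  }
  if (!is.null(X)) {
    qx <- qr(cbind(1, X))
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  sxx <- sum(x^2)
  b <- sum(x * y) / sxx
  df <- n - k - 2L
  sigma2 <- max(0, sum(y^2) - b^2 * sxx) / df
  se <- sqrt(sigma2 / sxx)
  z2 <- if (se > 0) (b / se)^2 else Inf
  tibble(b = b, se = se, p = pchisq(z2, 1, lower.tail = FALSE), n = n,
         reason = NA_character_)
}

#' Scan one gene: all isoforms against all cis SNPs
#'
#' @param genotypes A [genotype_matrix()] restricted or not to the cis
#'   window; `snp_ids` selects columns.
#' @param abundance An [abundance_matrix()] (post-preprocessing).
#' @param gene_id Gene to scan; its isoforms are taken from the abundance
#'   feature map.
#' @param covariates Optional samples x k matrix aligned with the shared
#'   samples.
#' @param snp_ids SNPs to test (default: all in `genotypes`).
#' @return Tibble with one row per (SNP, isoform): `snp_id`, `isoform_id`,
#'   `gene_id`, `b`, `se`, `n`, `p`, `reason`. Deterministic ordering by
#'   (snp, isoform).
#' @export
scan_gene <- function(genotypes, abundance, gene_id, covariates = NULL,
                      snp_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(abundance, "abundance_matrix"))
  iso <- abundance$features$feature_id[abundance$features$gene_id == gene_id]
  if (length(iso) < 2) abort("gene needs >= 2 retained isoforms.")
  snp_ids <- snp_ids %||% genotypes$snps$snp_id
  shared <- intersect(sample_ids(genotypes), sample_ids(abundance))
  if (length(shared) < 3) abort("too few shared samples.")
  X <- genotypes$dosages[shared, snp_ids, drop = FALSE]
  Y <- abundance$values[shared, iso, drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[shared, , drop = FALSE]
    qx <- qr(cbind(1, covariates))
    Y <- qr.resid(qx, Y)
  } else {
    Y <- sweep(Y, 2, colMeans(Y))
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(shared)
  df <- n - k - 2L
  res <- lapply(snp_ids, function(s) {
    x <- X[, s]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (!is.null(covariates)) x <- qr.resid(qx, x) else x <- x - mean(x)
    sxx <- sum(x^2)
    if (sxx == 0) {
      return(tibble(snp_id = s, isoform_id = iso, gene_id = gene_id,
                    b = NA_real_, se = NA_real_, n = n, p = NA_real_,
                    reason = "monomorphic"))
    }
    b <- unname(drop(crossprod(x, Y))) / sxx
    sigma2 <- unname(pmax(0, colSums(Y^2) - b^2 * sxx)) / df
    se <- sqrt(sigma2 / sxx)
    p <- pchisq(ifelse(se > 0, (b / se)^2, Inf), 1, lower.tail = FALSE)
    tibble(snp_id = s, isoform_id = iso, gene_id = gene_id,
           b = b, se = se, n = n, p = p, reason = NA_character_)
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$snp_id, .data$isoform_id)
}
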