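# End-to-end sQTL scans: individual-level (genotypes + abundance) and
# summary-level (isoform-eQTL table + theta).

#' Individual-level cis-sQTL scan
#'
#' For every gene with at least two retained isoforms: fits per-isoform
#' eQTL regressions for every SNP in the gene's cis window, estimates the
#' error-correlation matrix theta from the abundance correlations (full
#' sample overlap), and runs the heterogeneity test per SNP.
#'
#' @inheritParams scan_gene
#' @inheritParams build_cis_windows
#' @inheritParams thistle_test
#' @param keep_isoform_eqtl If TRUE, the per-isoform eQTL summary table is
#'   attached as attribute `"isoform_eqtl"` (needed to re-run the
#'   summary-level path on the same data).
#' @return A tibble of class `thistle_scan`, one row per gene-SNP pair:
#'   `gene_id`, `snp_id`, `m`, `q`, `n_lambda`, `statistic`, `p`,
#'   `method`, `reason`.
#' @export
thistle_scan <- function(genotypes, abundance, gene_models,
                         covariates = NULL, window = 2e6,
                         anchor = c("gene", "tss"),
                         method = c("saddlepoint", "davies", "montecarlo"),
                         eig_tol = 1e-8, keep_isoform_eqtl = FALSE) {
  method <- match.arg(method)
  gene_models <- ensure_isoform_counts(gene_models, abundance)
  cis <- build_cis_windows(gene_models, genotypes$snps, window = window,
                           anchor = match.arg(anchor))
  eqtl_tabs <- list()
  res <- purrr::imap(cis, function(snp_ids, gid) {
    if (length(snp_ids) == 0) return(NULL)
    tab <- scan_gene(genotypes, abundance, gid, covariates = covariates,
                     snp_ids = snp_ids)
    if (keep_isoform_eqtl) eqtl_tabs[[gid]] <<- tab
    iso <- abundance$features$feature_id[abundance$features$gene_id == gid]
    shared <- intersect(sample_ids(genotypes), sample_ids(abundance))
    theta <- theta_from_abundance(abundance$values[shared, iso, drop = FALSE])
    test_table(tab, theta, iso, method = method, eig_tol = eig_tol)
  })
  out <- dplyr::bind_rows(res)
  if (keep_isoform_eqtl) {
    attr(out, "isoform_eqtl") <- dplyr::bind_rows(eqtl_tabs)
  }
  class(out) <- c("thistle_scan", class(out))
  out
}

#' Summary-level cis-sQTL scan
#'
#' Runs the heterogeneity test from isoform-eQTL summary statistics alone.
#' Unless supplied, theta is estimated per gene from the correlation of
#' effect estimates across null SNPs ([theta_from_null_snps()]).
#'
#' @param table Isoform-eQTL summary table: tibble with `snp_id`,
#'   `isoform_id`, `gene_id`, `b`, `se`, `n`, `p`.
#' @param theta Optional named list gene id -> correlation matrix; when
#'   NULL it is estimated from null SNPs.
#' @inheritParams theta_from_null_snps
#' @inheritParams thistle_test
#' @return A `thistle_scan` tibble (see [thistle_scan()]).
#' @export
thistle_from_summary <- function(table, theta = NULL, p_threshold = 0.01,
                                 min_null = 30,
                                 method = c("saddlepoint", "davies",
                                            "montecarlo"),
                                 eig_tol = 1e-8) {
  method <- match.arg(method)
  table <- as_tibble(table)
  res <- lapply(split(table, table$gene_id), function(tab) {
    gid <- tab$gene_id[1]
    iso <- sort(unique(tab$isoform_id))
    th <- theta[[gid]] %||%
      theta_from_null_snps(tab, p_threshold = p_threshold,
                           min_null = min_null)
    if (!is.null(dimnames(th))) th <- th[iso, iso, drop = FALSE]
    test_table(tab, th, iso, method = method, eig_tol = eig_tol)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("thistle_scan", class(out))
  out
}

# Applies the heterogeneity test to every SNP in a per-gene summary table.
test_table <- function(tab, theta, iso, method, eig_tol) {
  gid <- tab$gene_id[1]
  by_snp <- split(tab, tab$snp_id)
  rows <- lapply(by_snp, function(d) {
    d <- d[match(iso, d$isoform_id), ]
    thistle_test(d$b, d$se, theta, gene_id = gid, snp_id = d$snp_id[1],
                 method = method, eig_tol = eig_tol)
  })
  dplyr::bind_rows(rows)
}

ensure_isoform_counts <- function(gene_models, abundance) {
  gene_models <- as_tibble(gene_models)
  if (!("isoform_ids" %in% names(gene_models)) &&
      !("n_isoforms" %in% names(gene_models))) {
    cnt <- table(abundance$features$gene_id)
    gene_models$n_isoforms <-
      as.integer(cnt[gene_models$gene_id])
    gene_models$n_isoforms[is.na(gene_models$n_isoforms)] <- 0L
  }
  gene_models
}
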