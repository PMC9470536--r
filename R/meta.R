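# Fixed-effect meta-analysis of isoform-eQTL effects across datasets with
# correlated estimation errors (overlapping or related samples), the step
# applied before the cross-cohort heterogeneity test.

#' Between-dataset error correlation from jointly-null SNPs
#'
#' Estimates the correlation of estimation errors between datasets as the
#' Pearson correlation of effect estimates over SNP-isoform pairs that are
#' null in all datasets (all per-dataset P above `p_threshold`), pooled
#' across isoforms. Falls back to independence (identity) with a warning
#' when too few jointly-null records are available.
#'
#' @param summaries Named list of isoform-eQTL summary tibbles (columns
#'   `snp_id`, `isoform_id`, `b`, `p`), one per dataset.
#' @param p_threshold Null-SNP P threshold (default 0.01).
#' @param min_null Minimum jointly-null records required (default 30).
#' @return D x D correlation matrix with dataset names as dimnames.
#' @export
estimate_dataset_correlation <- function(summaries, p_threshold = 0.01,
                                         min_null = 30) {
  D <- length(summaries)
  ids <- names(summaries) %||% paste0("dataset", seq_len(D))
  if (D < 2) abort("need >= 2 datasets.")
  key <- function(d) paste(d$snp_id, d$isoform_id, sep = "\r")
  base <- as_tibble(summaries[[1]])[, c("snp_id", "isoform_id")]
  keys <- key(base)
  B <- matrix(NA_real_, length(keys), D, dimnames = list(NULL, ids))
  P <- B
  for (i in seq_len(D)) {
    d <- as_tibble(summaries[[i]])
    idx <- match(keys, key(d))
    B[, i] <- d$b[idx]
    P[, i] <- d$p[idx]
  }
  null_all <- rowSums(P > p_threshold & is.finite(B)) == D
  if (sum(null_all) < min_null) {
    warn(sprintf(
      "only %d jointly-null SNP-isoform records (< %d); assuming independent errors",
      sum(null_all), min_null))
    Cfb <- diag(D)
    dimnames(Cfb) <- list(ids, ids)
    return(Cfb)
  }
  nearest_correlation(cor(B[null_all, , drop = FALSE]))
}

#' Correlated-error fixed-effect meta-analysis of one effect
#'
#' Generalized-least-squares fixed-effect estimate: with
#' `Omega_ij = C_ij * se_i * se_j`,
#' `b_meta = (1' Omega^-1 1)^-1 1' Omega^-1 b` and
#' `se_meta = sqrt((1' Omega^-1 1)^-1)`; the P-value is the chi-square(1)
#' upper tail of `(b_meta / se_meta)^2`. With `C = I` this is exactly
#' inverse-variance-weighted meta-analysis.
#'
#' @param b Effect estimates across D datasets.
#' @param se Positive standard errors.
#' @param C D x D error correlation matrix (default identity).
#' @return One-row tibble `b_meta`, `se_meta`, `p`.
#' @export
meta_effect <- function(b, se, C = diag(length(b))) {
  D <- length(b)
  stopifnot(length(se) == D)
  if (any(se <= 0)) abort("`se` must be strictly positive.")
  if (D == 1) {
    return(tibble(b_meta = b, se_meta = se,
                  p = pchisq((b / se)^2, 1, lower.tail = FALSE)))
  }
  check_correlation_matrix(C, "C")
  Omega <- C * tcrossprod(se)
  inv <- tryCatch(solve(Omega), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    warn("singular Omega; applying ridge repair")
    Omega <- Omega + diag(1e-10 * mean(diag(Omega)), D)
    inv <- solve(Omega)
  }
  one <- rep(1, D)
  denom <- drop(crossprod(one, inv %*% one))
  b_meta <- drop(crossprod(one, inv %*% b)) / denom
  se_meta <- sqrt(1 / denom)
  tibble(b_meta = b_meta, se_meta = se_meta,
         p = pchisq((b_meta / se_meta)^2, 1, lower.tail = FALSE))
}

#' Meta-analyze isoform-eQTL summary tables across datasets
#'
#' Harmonizes the (SNP, isoform) key space across datasets and applies
#' [meta_effect()] record by record with a shared between-dataset error
#' correlation matrix.
#'
#' @inheritParams estimate_dataset_correlation
#' @param C Optional precomputed error correlation; estimated from
#'   jointly-null SNPs when NULL.
#' @return Merged isoform-eQTL tibble: `snp_id`, `isoform_id`, `gene_id`,
#'   `b`, `se`, `n`, `p`, `n_datasets`.
#' @export
meta_analyze <- function(summaries, C = NULL, p_threshold = 0.01,
                         min_null = 30) {
  D <- length(summaries)
  if (D < 2) abort("need >= 2 datasets.")
  C <- C %||% estimate_dataset_correlation(summaries, p_threshold,
                                           min_null)
  all_tab <- dplyr::bind_rows(
    purrr::imap(summaries,
                function(d, id) dplyr::mutate(as_tibble(d), .dataset = id)))
  dataset_ids <- colnames(C) %||% unique(all_tab$.dataset)
  groups <- split(all_tab, paste(all_tab$gene_id, all_tab$snp_id,
                                 all_tab$isoform_id, sep = "\r"))
  rows <- lapply(groups, function(d) {
    base <- tibble(snp_id = d$snp_id[1], isoform_id = d$isoform_id[1],
                   gene_id = d$gene_id[1])
    ok <- is.finite(d$b) & is.finite(d$se) & d$se > 0
    if (!any(ok)) {
      return(dplyr::bind_cols(base, tibble(
        b = NA_real_, se = NA_real_, n = sum(d$n), p = NA_real_,
        n_datasets = 0L)))
    }
    idx <- match(d$.dataset[ok], dataset_ids)
    me <- meta_effect(d$b[ok], d$se[ok], C[idx, idx, drop = FALSE])
    dplyr::bind_cols(base, tibble(b = me$b_meta, se = me$se_meta,
                                  n = sum(d$n[ok]), p = me$p,
                                  n_datasets = sum(ok)))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$gene_id, .data$snp_id,
                 .data$isoform_id)
}
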