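# Fold-enrichment of a query SNP set (e.g. lead cis-sQTL SNPs) in genomic
# annotation categories, against control SNP sets resampled from the
# tested cis-SNP pool with matched MAF and TSS-distance distributions.

#' Annotate SNPs with interval-track membership
#'
#' Adds one logical column per track: TRUE when the SNP's (1-based)
#' position falls inside at least one interval. Tracks use the BED
#' convention: 0-based half-open `[start, end)`, so 1-based position `p`
#' is inside when `start < p <= end`.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos` (1-based).
#' @param tracks Named list of tibbles with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @return `snps` with one logical membership column per track.
#' @export
annotate_snps <- function(snps, tracks) {
  snps <- as_tibble(snps)
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    abort("`tracks` must be a named list.")
  }
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  for (nm in names(tracks)) {
    tr <- as_tibble(tracks[[nm]])
    if (any(tr$start >= tr$end)) abort("intervals need start < end.")
    tr_gr <- GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(tr$start + 1L, tr$end))  # to 1-based closed
    snps[[nm]] <- GenomicRanges::countOverlaps(snp_gr, tr_gr) > 0
  }
  snps
}

# Joint (MAF bin, |TSS distance| bin) stratum labels over the pool's
# feature space; query SNPs must live inside it.
matching_strata <- function(pool, n_maf_bins = 10, n_dist_bins = 10) {
  maf_breaks <- seq(0, 0.5, length.out = n_maf_bins + 1)
  dist_breaks <- unique(quantile(abs(pool$tss_dist),
                                 probs = seq(0, 1, length.out = n_dist_bins + 1)))
  list(maf = maf_breaks, dist = dist_breaks)
}

stratum_of <- function(snps, strata) {
  mb <- cut(snps$maf, strata$maf, include.lowest = TRUE, labels = FALSE)
  db <- cut(abs(snps$tss_dist), strata$dist, include.lowest = TRUE,
            labels = FALSE)
  db[is.na(db)] <- length(strata$dist) - 1  # beyond pool range: top bin
  paste(mb, db, sep = ":")
}

#' Sample MAF- and TSS-distance-matched control SNP sets
#'
#' Draws `n_sets` control sets from the pool, each with exactly as many
#' SNPs as the query, stratified by the joint (MAF bin, absolute
#' TSS-distance bin): within each stratum the control count equals the
#' query count. Query SNPs are excluded from the candidate pool. Sampling
#' is without replacement within a set and independent across sets.
#'
#' @param query,pool Tibbles with `snp_id`, `maf`, `tss_dist` (signed or
#'   absolute distance to the nearest TSS) plus any annotation columns.
#'   Every query SNP must also satisfy the pool's feature ranges.
#' @param n_sets Number of control sets (default 1000).
#' @param seed Integer seed.
#' @param n_maf_bins,n_dist_bins Matching resolution: equal-width MAF bins
#'   over (0, 0.5\] and quantile bins of the pool's absolute TSS distance.
#' @return List of integer vectors, each indexing rows of `pool`.
#' @export
sample_controls <- function(query, pool, n_sets = 1000, seed = 1L,
                            n_maf_bins = 10, n_dist_bins = 10) {
  query <- as_tibble(query)
  pool <- as_tibble(pool)
  strata <- matching_strata(pool, n_maf_bins, n_dist_bins)
  q_str <- stratum_of(query, strata)
  p_str <- stratum_of(pool, strata)
  eligible <- !(pool$snp_id %in% query$snp_id)
  q_counts <- table(q_str)
  cand <- lapply(names(q_counts),
                 function(s) which(eligible & p_str == s))
  names(cand) <- names(q_counts)
  short <- vapply(cand, length, integer(1)) < as.integer(q_counts)
  if (any(short)) {
    abort(paste0(
      "stratum (maf_bin:dist_bin) without enough non-query candidates: ",
      paste(names(q_counts)[short], collapse = ", "),
      "; coarsen the matching bins."))
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    unlist(lapply(names(q_counts), function(s) {
      cand[[s]][sample.int(length(cand[[s]]), q_counts[[s]])]
    }), use.names = FALSE)
  })
}

#' Fold enrichment of a query SNP set in one annotation category
#'
#' `fold = p_query / mean(p_control)`, the query's category membership
#' proportion over the mean proportion across control sets. The standard
#' error follows the Delta method for a ratio of independent estimates:
#' `SE^2 = fold^2 * (var(p_q)/p_q^2 + var(p_c_bar)/p_c_bar^2)` with a
#' binomial variance for the query proportion and the empirical
#' between-set variance divided by the number of sets for the control
#' mean. The 95% CI is `fold +/- 1.96 SE`, floored at 0.
#'
#' @param query Annotated query tibble (see [annotate_snps()]).
#' @param pool Annotated pool tibble the control indices refer to.
#' @param control_sets List of pool row-index vectors from
#'   [sample_controls()].
#' @param category Name of a logical annotation column.
#' @return One-row tibble: `category`, `p_query`, `p_control`, `fold`,
#'   `se`, `ci_low`, `ci_high`, `n_control_sets`. `fold` is NA (with the
#'   proportions still reported) when the mean control proportion is 0.
#' @export
fold_enrichment <- function(query, pool, control_sets, category) {
  if (length(control_sets) < 100) {
    abort("need >= 100 control sets for a stable null mean.")
  }
  qf <- query[[category]]
  pf <- pool[[category]]
  if (is.null(qf) || is.null(pf)) abort(sprintf("no column `%s`.", category))
  p_q <- mean(qf)
  p_c <- vapply(control_sets, function(idx) mean(pf[idx]), numeric(1))
  p_c_bar <- mean(p_c)
  n_sets <- length(control_sets)
  if (p_c_bar == 0) {
    return(tibble(category = category, p_query = p_q, p_control = 0,
                  fold = NA_real_, se = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, n_control_sets = n_sets))
  }
  fold <- p_q / p_c_bar
  var_q <- p_q * (1 - p_q) / length(qf)
  var_c <- var(p_c) / n_sets
  se <- if (p_q > 0) {
    fold * sqrt(var_q / p_q^2 + var_c / p_c_bar^2)
  } else {
    sqrt(var_q) / p_c_bar  # ratio SE degenerates at p_q = 0
  }
  tibble(category = category, p_query = p_q, p_control = p_c_bar,
         fold = fold, se = se, ci_low = max(0, fold - 1.96 * se),
         ci_high = fold + 1.96 * se, n_control_sets = n_sets)
}

#' Enrichment report across several categories
#'
#' Convenience wrapper: samples matched controls once and computes
#' [fold_enrichment()] for each named category column.
#'
#' @inheritParams sample_controls
#' @param categories Character vector of logical annotation columns
#'   (default: all logical columns shared by query and pool).
#' @param ... Passed to [sample_controls()].
#' @return Tibble of class `enrichment_report`, one row per category.
#' @export
enrichment_report <- function(query, pool, categories = NULL,
                              n_sets = 1000, seed = 1L, ...) {
  query <- as_tibble(query)
  pool <- as_tibble(pool)
  if (is.null(categories)) {
    shared <- intersect(names(query), names(pool))
    categories <- shared[vapply(query[shared], is.logical, logical(1))]
  }
  if (length(categories) == 0) abort("no annotation categories found.")
  sets <- sample_controls(query, pool, n_sets = n_sets, seed = seed, ...)
  out <- dplyr::bind_rows(
    lapply(categories,
           function(cc) fold_enrichment(query, pool, sets, cc)))
  class(out) <- c("enrichment_report", class(out))
  out
}

#' Simulate a synthetic cis-SNP pool for the enrichment bench
#'
#' Generates a pool with uniform MAF in (0.01, 0.5), Laplace-like signed
#' TSS distances, and one or more logical annotation categories with given
#' prevalence. Purely synthetic; it emulates only the feature space the
#' matching operates on.
#'
#' @param n_snps Pool size.
#' @param prevalence Named numeric vector: baseline membership probability
#'   per category.
#' @param seed Integer seed.
#' @return Tibble: `snp_id`, `chrom`, `pos`, `maf`, `tss_dist`, plus one
#'   logical column per category.
#' @export
simulate_snp_pool <- function(n_snps = 5e4,
                              prevalence = c(annot = 0.1), seed = 1L) {
  set.seed(seed)
  pool <- tibble(
    snp_id = paste0("rs", seq_len(n_snps)),
    chrom = "1",
    pos = sort(sample.int(2e8, n_snps)),
    maf = runif(n_snps, 0.01, 0.5),
    tss_dist = round(rexp(n_snps, rate = 1 / 2e4) *
                       sample(c(-1, 1), n_snps, replace = TRUE)))
  for (nm in names(prevalence)) {
    pool[[nm]] <- runif(n_snps) < prevalence[[nm]]
  }
  pool
}
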