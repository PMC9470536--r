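# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @rdname thistle_scan_tidiers
#' @param x A `thistle_scan` object.
#' @param ... Unused.
tidy.thistle_scan <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidiers for sQTL scan results
#'
#' `tidy()` returns the per-(gene, SNP) result rows as a plain tibble;
#' `glance()` returns a one-row scan summary including the number of
#' genes with a genome-wide-significant sQTL (`sig_threshold`, default
#' 5e-8).
#'
#' @param x A `thistle_scan` object.
#' @param sig_threshold Significance threshold for `n_sgenes`.
#' @param ... Unused.
#' @name thistle_scan_tidiers
#' @export
glance.thistle_scan <- function(x, sig_threshold = 5e-8, ...) {
  lead <- dplyr::slice_min(dplyr::group_by(as_tibble(x), .data$gene_id),
                           .data$p, n = 1, with_ties = FALSE)
  tibble(n_genes = dplyr::n_distinct(x$gene_id),
         n_tests = sum(!is.na(x$p)),
         n_skipped = sum(is.na(x$p)),
         min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
         n_sgenes = sum(lead$p <= sig_threshold, na.rm = TRUE),
         sig_threshold = sig_threshold)
}

#' Plot an sQTL scan
#'
#' -log10 P per tested SNP, grouped by gene, with a reference line at the
#' genome-wide threshold.
#'
#' @param object A `thistle_scan` tibble.
#' @param sig_threshold Reference line (default 5e-8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thistle_scan <- function(object, sig_threshold = 5e-8, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$p))
  d <- dplyr::mutate(dplyr::group_by(d, .data$gene_id),
                     idx = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(.data$idx, -log10(.data$p),
                                  colour = .data$gene_id)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(sig_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "SNP index within cis window",
                  y = expression(-log[10](italic(P))),
                  colour = "gene") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname enrichment_report_tidiers
tidy.enrichment_report <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidiers for enrichment reports
#'
#' @param x An `enrichment_report`.
#' @param ... Unused.
#' @name enrichment_report_tidiers
#' @export
glance.enrichment_report <- function(x, ...) {
  tibble(n_categories = nrow(x),
         n_enriched = sum(x$ci_low > 1, na.rm = TRUE),
         n_depleted = sum(x$ci_high < 1, na.rm = TRUE),
         n_control_sets = x$n_control_sets[1])
}

#' Plot fold enrichment with 95% confidence intervals
#'
#' Column chart of fold enrichment per annotation category, error bars
#' from the Delta-method CI, dashed line at no enrichment.
#'
#' @param object An `enrichment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_report <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$fold)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "fold enrichment") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-isoform eQTL effects at one variant
#'
#' Visualizes the heterogeneity the sQTL test measures: each isoform's
#' effect estimate with its 95% CI at a chosen SNP.
#'
#' @param table Isoform-eQTL table (e.g. from [scan_gene()]).
#' @param snp_id SNP to display.
#' @param gene_id Optional gene filter.
#' @return A ggplot object.
#' @export
plot_isoform_effects <- function(table, snp_id, gene_id = NULL) {
  d <- dplyr::filter(as_tibble(table), .data$snp_id == !!snp_id)
  if (!is.null(gene_id)) d <- dplyr::filter(d, .data$gene_id == !!gene_id)
  if (nrow(d) == 0) abort("no rows for that SNP.")
  ggplot2::ggplot(d, ggplot2::aes(.data$b, .data$isoform_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$b - 1.96 * .data$se,
                   xmax = .data$b + 1.96 * .data$se), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "isoform-eQTL effect (95% CI)", y = NULL,
                  title = snp_id) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
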