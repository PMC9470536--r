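# Light S3 containers. Dosage and abundance values stay numeric matrices
# (samples in rows); per-feature metadata rides along as a tibble.

#' Construct a genotype matrix
#'
#' @param dosages Numeric matrix, samples x SNPs, values in \[0, 2\] with NA
#'   allowed for missing genotypes. Row names are sample ids, column names
#'   SNP ids (or supply `snps$snp_id`).
#' @param snps Tibble/data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos` (1-based), and optionally `ref`, `alt`. Defaults to bare ids.
#' @return An object of class `genotype_matrix`: list with `dosages` and
#'   `snps` (with a `maf` column computed from the dosages).
#' @export
genotype_matrix <- function(dosages, snps = NULL) {
  stopifnot(is.matrix(dosages))
  if (is.null(colnames(dosages)) && !is.null(snps)) {
    colnames(dosages) <- snps$snp_id
  }
  if (is.null(snps)) {
    snps <- tibble(snp_id = colnames(dosages),
                   chrom = NA_character_, pos = NA_integer_,
                   ref = NA_character_, alt = NA_character_)
  }
  snps <- as_tibble(snps)
  if (anyDuplicated(snps$snp_id)) abort("duplicate SNP ids.")
  if (!is.null(rownames(dosages)) && anyDuplicated(rownames(dosages))) {
    abort("duplicate sample ids.")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    abort("dosage values must lie in [0, 2].")
  }
  snps$maf <- unname(apply(dosages, 2, maf_from_dosage))
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  print(head(x$snps), ...)
  invisible(x)
}

#' Construct an abundance matrix
#'
#' @param values Numeric matrix, samples x features (TPM before
#'   normalization, arbitrary reals after). Column names are feature ids.
#' @param features Tibble/data frame with `feature_id` and `gene_id`
#'   mapping every feature to exactly one gene.
#' @param level `"isoform"` or `"gene"`.
#' @return Object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, features, level = c("isoform", "gene")) {
  level <- match.arg(level)
  stopifnot(is.matrix(values))
  features <- as_tibble(features)
  if (anyDuplicated(features$feature_id)) abort("duplicate feature ids.")
  if (!setequal(colnames(values), features$feature_id)) {
    abort("`features$feature_id` must match the columns of `values`.")
  }
  features <- features[match(colnames(values), features$feature_id), ]
  structure(list(values = values, features = features, level = level),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix level=%s> %d samples x %d features (%d genes)\n",
              x$level, nrow(x$values), ncol(x$values),
              dplyr::n_distinct(x$features$gene_id)))
  invisible(x)
}

sample_ids <- function(x) {
  rownames(if (inherits(x, "genotype_matrix")) x$dosages else x$values)
}
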