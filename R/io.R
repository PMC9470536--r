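# Readers and writers for the on-disk artifacts: genotypes (VCF or dosage
# matrix TSV), abundance TSV, gene models (TSV or GFF/GTF), isoform-eQTL
# summary TSV, BED annotation tracks, and result tables. All tabular IO
# goes through readr; VCF through vcfR; GFF/BED through rtracklayer.

#' Read genotype dosages
#'
#' VCF dosages come from the `DS` FORMAT field when present, else from the
#' `GT` allele count (`dosage_field` forces one). Missing genotypes
#' (`./.`) are recorded as NA, never as 0. Multi-allelic records are
#' skipped (`multiallelic = "skip"`) or rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"` (TSV with
#'   a `sample_id` column and one numeric column per SNP, as written by
#'   [write_genotypes()]).
#' @param dosage_field `"auto"`, `"DS"` or `"GT"`.
#' @param multiallelic `"skip"` or `"error"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           dosage_field = c("auto", "DS", "GT"),
                           multiallelic = c("skip", "error")) {
  format <- match.arg(format)
  dosage_field <- match.arg(dosage_field)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  }
  if (format == "matrix") return(read_genotype_matrix(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    if (multiallelic == "error") abort("multi-allelic records present.")
    inform(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  keep <- !multi
  ids_all <- fix$ID
  blank <- is.na(ids_all) | ids_all == "."
  ids_all[blank] <- paste0(fix$CHROM, ":", fix$POS)[blank]
  if (anyDuplicated(ids_all[keep])) {
    abort(paste0("duplicate SNP id(s): ",
                 paste(unique(ids_all[keep][duplicated(ids_all[keep])]),
                       collapse = ", ")))
  }
  has_ds <- "DS" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID
  use_ds <- dosage_field == "DS" || (dosage_field == "auto" && has_ds)
  if (use_ds && !has_ds) abort("no DS field in FORMAT.")
  if (use_ds) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  dos <- t(dos[keep, , drop = FALSE])  # samples x SNPs
  ids <- ids_all[keep]
  colnames(dos) <- ids
  genotype_matrix(dos, tibble(snp_id = ids, chrom = fix$CHROM[keep],
                              pos = as.integer(fix$POS[keep]),
                              ref = fix$REF[keep], alt = fix$ALT[keep]))
}

read_genotype_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(d)[1] != "sample_id") abort("matrix file needs a `sample_id` column.")
  m <- as.matrix(d[-1])
  check_all_numeric(m, path)
  storage.mode(m) <- "double"
  rownames(m) <- d$sample_id
  if (anyDuplicated(colnames(m))) abort("duplicate SNP ids in header.")
  genotype_matrix(m)
}

#' Write genotype dosages as a TSV matrix
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  d <- as_tibble(genotypes$dosages)
  d <- dplyr::bind_cols(tibble(sample_id = sample_ids(genotypes)), d)
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read an abundance matrix
#'
#' TSV with a `sample_id` column and one numeric column per feature
#' (samples in rows), or transposed (`orientation = "features_in_rows"`,
#' first column `feature_id`). Features absent from the gene map are an
#' error in strict mode, or dropped with a message otherwise.
#'
#' @param path File path.
#' @param gene_map Tibble (or TSV path) with `feature_id`, `gene_id`.
#' @param orientation See above.
#' @param level `"isoform"` or `"gene"`.
#' @param strict Reject unmapped features (default TRUE).
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path, gene_map,
                           orientation = c("features_in_columns",
                                           "features_in_rows"),
                           level = "isoform", strict = TRUE) {
  orientation <- match.arg(orientation)
  if (is.character(gene_map)) {
    gene_map <- readr::read_tsv(gene_map, show_col_types = FALSE)
  }
  gene_map <- as_tibble(gene_map)
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (orientation == "features_in_columns") {
    m <- as.matrix(d[-1])
    rownames(m) <- d[[1]]
  } else {
    m <- t(as.matrix(d[-1]))
    colnames(m) <- d[[1]]
  }
  check_all_numeric(m, path)
  storage.mode(m) <- "double"
  unmapped <- setdiff(colnames(m), gene_map$feature_id)
  if (length(unmapped) > 0) {
    if (strict) {
      abort(paste0("feature(s) absent from gene map: ",
                   paste(head(unmapped, 5), collapse = ", "),
                   if (length(unmapped) > 5) ", ..."))
    }
    inform(sprintf("dropping %d unmapped feature(s)", length(unmapped)))
    m <- m[, setdiff(colnames(m), unmapped), drop = FALSE]
  }
  feats <- gene_map[match(colnames(m), gene_map$feature_id), ]
  abundance_matrix(m, feats, level = level)
}

#' Write an abundance matrix as TSV (samples in rows)
#'
#' @param abundance An [abundance_matrix()].
#' @param path Output path.
#' @export
write_abundance <- function(abundance, path) {
  d <- as_tibble(abundance$values)
  d <- dplyr::bind_cols(tibble(sample_id = sample_ids(abundance)), d)
  readr::write_tsv(d, path)
  invisible(path)
}

check_all_numeric <- function(m, path) {
  if (is.numeric(m)) return(invisible(TRUE))
  bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                 !is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell in %s at row %d, column `%s`: \"%s\"",
                  path, bad[1, 1], colnames(m)[bad[1, 2]],
                  m[bad[1, 1], bad[1, 2]]))
  }
  invisible(TRUE)
}

#' Read isoform-eQTL summary statistics
#'
#' TSV with columns `snp_id`, `isoform_id`, `gene_id`, `b`, `se`, `n`,
#' `p`. Rows with `se <= 0` are rejected (warning with row indices). When
#' `check_consistency`, P-values are compared with the chi-square tail of
#' `(b/se)^2` and mismatches beyond 10% relative are flagged with a
#' warning.
#'
#' @param path File path.
#' @param check_consistency Verify p against b/se (default TRUE).
#' @return Typed tibble.
#' @export
read_summary_stats <- function(path, check_consistency = TRUE) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("snp_id", "isoform_id", "gene_id", "b", "se", "n", "p")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  d <- d[need]
  bad_se <- which(!is.na(d$se) & d$se <= 0)
  if (length(bad_se) > 0) {
    warn(paste0("rejecting row(s) with se <= 0: ",
                paste(head(bad_se, 10), collapse = ", ")))
    d <- d[-bad_se, ]
  }
  if (any(!is.na(d$p) & (d$p <= 0 | d$p > 1))) {
    abort("p-values must lie in (0, 1].")
  }
  if (check_consistency) {
    p_z <- pchisq((d$b / d$se)^2, 1, lower.tail = FALSE)
    off <- is.finite(p_z) & is.finite(d$p) & p_z > 1e-300 &
      abs(log(d$p / p_z)) > log(1.1)
    if (any(off)) {
      warn(sprintf("%d row(s) with p inconsistent with b/se beyond 10%%",
                   sum(off)))
    }
  }
  d
}

#' Write an isoform-eQTL summary table
#' @param table Tibble as returned by [scan_gene()] or [meta_analyze()].
#' @param path Output path.
#' @export
write_summary_stats <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

#' Read gene models
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand` and
#' optionally `isoforms` (comma-separated isoform ids), or a GFF/GTF file
#' (via rtracklayer) from whose `gene` and `transcript` features the table
#' is assembled. The TSS is `start` on the + strand and `end` on the -
#' strand; the cis window itself is strand-symmetric.
#'
#' @param path File path (`.gff`, `.gff3`, `.gtf` trigger GFF parsing).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   and `isoform_ids` list-column when isoform info is present.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.(gff3?|gtf)(\\.gz)?$", path, ignore.case = TRUE)) {
    return(read_gene_models_gff(path))
  }
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(d$start <= 0)) abort("coordinates are 1-based; start must be > 0.")
  d$tss <- ifelse(d$strand == "-", d$end, d$start)
  if ("isoforms" %in% names(d)) {
    d$isoform_ids <- strsplit(d$isoforms, ",", fixed = TRUE)
    d$isoforms <- NULL
  }
  d
}

read_gene_models_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF/GTF requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  is_tx <- md$type %in% c("transcript", "mRNA")
  genes <- tibble(
    gene_id = as.character(md$gene_id[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  tx_gene <- as.character(md$gene_id[is_tx])
  tx_id <- as.character(md$transcript_id[is_tx])
  genes$isoform_ids <- unname(split(tx_id, tx_gene)[genes$gene_id])
  genes
}

#' Read a BED annotation track
#'
#' Returns intervals in the BED convention itself: 0-based half-open
#' `[start, end)`, sorted within chromosome.
#'
#' @param path BED file path.
#' @return Tibble: `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading BED requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$name <- nm
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write sQTL scan results
#'
#' Deterministic column order, rows ordered by (gene, SNP), floating
#' values at 6 significant digits (tiny P-values keep their exponent).
#'
#' @param results A `thistle_scan` tibble.
#' @param path Output path.
#' @param digits Significant digits for floating columns.
#' @export
write_results <- function(results, path, digits = 6) {
  results <- as_tibble(results)
  cols <- c("gene_id", "snp_id", "m", "q", "n_lambda", "statistic", "p",
            "method", "reason")
  cols <- c(intersect(cols, names(results)),
            setdiff(names(results), cols))
  out <- dplyr::arrange(results[cols], .data$gene_id, .data$snp_id)
  for (cc in names(out)) {
    if (is.double(out[[cc]])) {
      out[[cc]] <- formatC(out[[cc]], digits = digits, format = "g")
      out[[cc]][out[[cc]] %in% c("NA", " NA")] <- NA_character_
    }
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read back an sQTL results TSV
#' @param path File path.
#' @return Tibble with typed columns.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
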