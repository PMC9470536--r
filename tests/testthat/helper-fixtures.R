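# Fixtures are built in code at test time; nothing binary on disk.

# Minimal VCF text with GT genotypes for 3 samples.
write_vcf_fixture <- function(path, gts = c("0/0", "0/1", "1/1"),
                              extra_records = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "1000", "rs1", "A", "G", ".", "PASS", ".", "GT", gts),
          collapse = "\t"),
    extra_records)
  writeLines(lines, path)
  path
}

vcf_record <- function(chrom = "1", pos, id, gts, ref = "A", alt = "G") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Small abundance matrix container with f isoforms of one gene.
toy_abundance <- function(values, gene = "g1") {
  m <- ncol(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(gene, ".iso", seq_len(m))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  abundance_matrix(values,
                   tibble::tibble(feature_id = colnames(values),
                                  gene_id = gene),
                   level = "isoform")
}

# Random valid correlation matrix of dimension m.
random_correlation <- function(m) {
  A <- matrix(rnorm(m * m), m)
  S <- crossprod(A) + diag(m) * 0.1
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

# Summary-level null draws: isoform effect estimates b ~ MVN(0, Sigma)
# with Sigma = theta * se se', across n_snps "null" SNPs.
simulate_null_effects <- function(n_snps, se, theta) {
  m <- length(se)
  Sigma <- theta * tcrossprod(se)
  MASS::mvrnorm(n_snps, mu = rep(0, m), Sigma = Sigma)
}
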