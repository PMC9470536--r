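Package: thistle
Title: Transcript-Level Splicing QTL Mapping via Heterogeneity of
    Isoform-eQTL Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genetic control of RNA splicing (cis-sQTLs) at the
    transcript level by testing for heterogeneity among per-isoform eQTL
    effects at a variant (the THISTLE test). Pairwise differences between
    isoform-eQTL effect estimates are standardized using their error
    correlation structure and combined into a quadratic-form statistic whose
    tail probability is evaluated by a saddlepoint approximation, with
    characteristic-function inversion and Monte Carlo oracles. Includes the
    surrounding pipeline: expression filtering, quantile normalization,
    rank-based inverse normal transformation, covariate residualization, SNP
    quality control, per-isoform cis-eQTL scans, correlated-error
    fixed-effect meta-analysis across datasets, an abundance-level
    simulation and calibration bench, and fold-enrichment of SNP sets in
    genomic annotations against MAF- and TSS-distance-matched resampled
    controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    MASS,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
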