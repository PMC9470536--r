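---
title: "Transcript-level sQTL mapping by isoform-effect heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-level sQTL mapping by isoform-effect heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thistle)
```

## The model

A splicing QTL (sQTL) changes how a gene's transcription is split across
its isoforms. If a variant `x` alters a splicing event, it is associated
with the *difference* in mature mRNA abundance between isoforms — even
when total expression is unchanged. The test therefore asks whether the
per-isoform eQTL effects of a variant are heterogeneous.

For a gene with `m ≥ 2` isoforms, each isoform's abundance `y_j`
(preprocessed, see below) is regressed on the dosage `x` with covariates,
giving effect estimates `b̂ = (b̂_1, …, b̂_m)` with standard errors
`S_j`. Jointly, `b̂ ~ MVN(b, S)`. All pairwise differences
`d̂_jk = b̂_j − b̂_k` (`j < k`, lexicographic order) are collected into a
length-`q` vector, `q = m(m−1)/2`, with covariance `V`:

* `var(d̂_jk) = S_j² + S_k² − 2 cov(b̂_j, b̂_k)`
* `cov(d̂_jk, d̂_gh) = cov(b̂_j,b̂_g) − cov(b̂_j,b̂_h) − cov(b̂_k,b̂_g) + cov(b̂_k,b̂_h)`
* `cov(b̂_j, b̂_k) = θ_jk S_j S_k`.

`θ_jk` is the correlation of the estimation errors of the two effects.
Because the isoforms are measured on (largely) the same individuals, the
errors are correlated even at null variants. Two estimators are provided:

1. **Individual-level** (`theta_from_overlap()`): `θ_jk ≈ r_p ρ`, where
   `ρ = n_s/√(n_j n_k)` is the sample overlap and `r_p` the Pearson
   correlation of the two isoforms' abundances in the overlapping
   samples. With a single fully-overlapping sample set this reduces to
   the abundance correlation matrix.
2. **Summary-level** (`theta_from_null_snps()`): the Pearson correlation
   of effect estimates across SNPs that are null for both isoforms
   (per-isoform P > 0.01 by default). At null SNPs the estimates are
   pure noise, so their correlation estimates the error correlation.

Standardizing, `z_jk = d̂_jk/√var(d̂_jk)`, gives `z ~ MVN(0, R)` under
the null of no heterogeneity, with `R` the correlation matrix implied by
`V`. The statistic is the unweighted quadratic form `T = z I zᵀ = Σ z²`,
distributed as `Σ λ_i χ²₁` with `λ` the eigenvalues of `R`.

The difference map annihilates the constant direction, so `rank(R) ≤ m−1`
structurally; eigenvalues at or below `1e-8 × λ_max` are discarded
(`eig_tol`). The tail distribution depends only on the nonzero spectrum,
so this changes nothing statistically and avoids spurious near-zero
modes.

## Tail probabilities

* `pvalue_saddlepoint()` — the default: Kuonen's Lugannani–Rice
  saddlepoint formula for quadratic forms in normals. When all
  eigenvalues are equal the saddle equation degenerates and the exact
  `χ²_q` closed form is used; near the distribution mean (|w| < 1e-4),
  where the formula is 0/0, it falls back to the inversion below.
* `pvalue_davies()` — numerical inversion of the characteristic
  function. Below the mean the classical Imhof-form integral is used.
  Above the mean the inversion contour is shifted to the saddlepoint
  abscissa, which turns the integrand into an exponentially tilted,
  non-cancelling form: relative accuracy is preserved down to
  `P ~ 1e-12` and beyond, where the untilted integral would lose the
  tail to floating-point cancellation. The achieved accuracy estimate is
  attached as an attribute; the `acc` parameter sets the request.
* `pvalue_montecarlo()` — direct simulation of `z ~ MVN(0, R)` with the
  add-one estimator; a model-free oracle used in tests.

P-values are clamped to `[1e-320, 1]` so output files never carry an
exact zero. Across 1,000 random spectra (dimension 1–45, eigenvalues
drawn from |N(0,1)|) the saddlepoint and inversion agree to
|Δlog₁₀P| < 0.05 throughout `P ∈ [1e-12, 0.5]` — the acceptance suite
re-verifies this on every run.

## Preprocessing conventions

Tunable thresholds live in `preprocess_config()`:

| parameter | default | meaning |
|---|---|---|
| `tpm_threshold` | 0.1 TPM | a value below this counts as unexpressed |
| `sample_fraction` | 0.8 | drop an isoform unexpressed in *strictly more than* this fraction |
| `maf_min` | 0.01 | minimum minor allele frequency (exclusive) |
| `hwe_p_min` | 1e-6 | Hardy–Weinberg exact-test floor (exclusive) |
| `call_rate_min` | 0.95 | genotyping rate floor (exclusive) |

Pipeline order: low-expression filter → per-sample quantile normalization
→ covariate residualization → rank-based inverse normal transform (RINT)
per isoform. Choices the literature leaves open, fixed here:

* Quantile normalization uses the mean-of-order-statistics reference
  (via `limma::normalizeQuantiles`), with ties averaged.
* RINT uses the Blom offset: `qnorm((rank − 3/8)/(n + 1/4))`, average
  ranks for ties. Both are the standard conventions.
* The Hardy–Weinberg exact test runs on hard calls (dosages rounded to
  0/1/2); exact tests are ill-defined on fractional imputed dosages.
* Missing dosages are stored as missing and mean-imputed per SNP only at
  regression time, common eQTL practice.
* Covariates (e.g. expression factors, genetic PCs) are accepted as
  input, not computed; the common factor-count schedule used with
  cohort RNA-seq (15 latent factors for n < 150, 30 for n < 250, 45 for
  n < 350, 60 above) is noted here for users assembling their own
  covariate tables.

The cis window is the gene body ± 2 Mb with closed boundaries, identical
on both strands; `anchor = "tss"` switches to a TSS-centred window.
Strand affects only the TSS definition (start on `+`, end on `−`). Genes
with a single isoform are excluded — no heterogeneity is defined.
Single-SNP regressions report the large-sample `χ²₁` P-value of
`(b/se)²` (one-sided chi-squared on the squared z-score).

Isoforms with missing estimates at a particular SNP are dropped and the
test re-formed with reduced `m`; if fewer than two remain a no-test
sentinel row is emitted with a reason code. Pair order is fixed
lexicographic; the statistic is invariant to isoform order (asserted in
tests), so the choice is cosmetic.

Pairwise θ estimates need not be jointly positive semi-definite, and an
indefinite θ can produce non-positive `var(d̂)`. All estimated
correlation matrices pass through `nearest_correlation()`: eigenvalues
clipped at zero, reconstructed, diagonal rescaled to 1. θ is estimated
per gene by default; pooling null SNPs across genes is possible by
concatenating tables but trades bias for variance and is left to the
user.

## Meta-analysis across datasets

Effects from multiple datasets are combined with a generalized
least-squares fixed-effect estimator that admits correlated estimation
errors (overlapping individuals between cohorts): with
`Ω_ij = C_ij se_i se_j`,

```
b_meta = (1ᵀΩ⁻¹1)⁻¹ 1ᵀΩ⁻¹ b̂,   se_meta = √((1ᵀΩ⁻¹1)⁻¹).
```

`C` is estimated from jointly-null SNP×isoform records, pooled across
isoforms by default (more stable than per-isoform estimates). With
`C = I` the estimator is exactly inverse-variance weighting; a singular
`Ω` (e.g. duplicated datasets) is ridge-repaired with `1e-10·mean(diag)`
and flagged. Heterogeneity statistics across datasets (Cochran's Q) and
random-effects weighting are deliberately out of scope.

## The simulation bench

`sim_config()` fixes the study conditions; the generator works at the
abundance level (read-level RNA-seq simulation is out of scope).

* **mvn mode** — isoform vector per sample: `μ0 + β·x + ε`,
  `ε ~ MVN(0, Σ)`, unit variances, common off-diagonal `residual_corr`.
  Baselines `μ0 ~ U(5, 50)`. Effects are in residual-SD units.
* **counts mode** — the same linear predictor on the log scale with a
  correlated Gaussian residual (SD 0.5) — a pure Poisson draw cannot
  carry the residual correlation the scenario grid specifies — then
  Poisson (`dispersion = 0`) or negative-binomial (size `1/dispersion`)
  counts, converted to TPM-like values as per-sample proportions × 1e6.
  The exact TPM pipeline of a quantifier like RSEM is not reproduced.

Scenarios: `null` (β = 0); `eqtl_only` (equal β across isoforms — an
expression effect the test must *not* reject); `sqtl` (β =
`effect_size` × a fixed zero-sum contrast with unit RMS, so there is no
net expression effect); `sqtl_plus_eqtl` (contrast plus a shared shift).
Genotypes are Binomial(2, maf) draws under Hardy–Weinberg.

What the bench emulates: the error-correlation structure that makes θ
necessary, overdispersion, compositional coupling of isoforms (counts
mode), and the null/eQTL/sQTL contrast of the schematic scenarios. What
it does not: linkage disequilibrium between SNPs, read-mapping noise,
isoform-quantification uncertainty from shared exons, or population
structure. Passing calibration here therefore shows the statistic is
correct under its model, not that real-data QC can be skipped.

Calibration summaries: `evaluate_fpr()` (Wilson 95% interval),
`evaluate_tpr()` (threshold sweeps), `compute_auc()` (Mann–Whitney with
ties counted half).

Problem sizes used by the acceptance suite, chosen as typical desk-scale
replication of the study conditions: 10,000 replicate genes per
abundance model for null calibration (n = 300, m = 3, MAF = 0.3,
residual correlation 0.5); effect grid {0.05, 0.1, 0.15, 0.2} at
n = 300 and n grid {100, 300, 1000} at effect 0.1, spanning low to high
power by the analytic normal approximation to the pairwise z-test;
50 genes × 200 cis-SNPs at n = 500 for the summary/individual
comparison; 5,000 null SNPs for θ recovery; 250 replicates for the
3-dataset meta-analysis power comparison.

## Enrichment against matched controls

`fold_enrichment()` computes, for a query SNP set (e.g. lead sQTL SNPs
per gene) and an annotation category, the ratio of the query's
membership proportion to the mean proportion across control sets
resampled from the tested cis-SNP pool. Controls are matched on the
joint distribution of MAF (10 equal-width bins over (0, 0.5]) and
absolute TSS distance (pool deciles); each control set has exactly the
query's stratum histogram, query SNPs excluded, sampling without
replacement within a set and independently across sets (1,000 sets by
default). Matching on absolute rather than signed TSS distance is this
package's choice; the binning is configurable.

The Delta method gives the sampling variance of the ratio:
`SE² ≈ fold² (var(p̂_q)/p̂_q² + var(p̄_c)/p̄_c²)`, binomial variance for
the query proportion, empirical between-set variance over the number of
sets for the control mean; the 95% CI is `fold ± 1.96·SE` floored at 0.
A zero control mean leaves the fold undefined and is reported as such
with the raw proportions. BED tracks are half-open 0-based; a 1-based
SNP position `p` is inside `[start, end)` iff `start < p ≤ end`.

## Numerical choices and degenerate inputs

* Saddle equation solved by `uniroot` on the bracketing interval
  `(−∞, 1/(2λ_max))`; tolerance 1e-14.
* Quadrature: adaptive `stats::integrate` with relative tolerance 1e-11,
  relaxed stepwise to 1e-7 if the rule reports roundoff; the achieved
  error estimate is propagated.
* `T = 0` (or equal effects) returns P = 1 exactly; monomorphic dosages
  yield a no-test sentinel, never P = NA silently dropped.
* Rank-deficient covariate matrices are an error naming the collinear
  columns; constant columns are absorbed by the intercept.
* All generators and resamplers take explicit integer seeds; derived
  sub-seeds stay below 2³¹.

## Known limitations

* The summary-level θ estimator needs enough null SNPs per isoform pair
  (default minimum 30); sparse cis windows with few tested SNPs should
  use the individual-level route.
* The GLS meta-analysis assumes a shared true effect across datasets;
  between-dataset effect heterogeneity is not modelled.
* Permutation-based gene-level FDR calibration is dataset-specific and
  out of scope; results report per-test P-values only.
* The statistic uses the identity weight matrix; alternative weightings
  of the pairwise differences are not implemented.
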