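---
title: "Evaluating type 1 diabetes genetic risk scores across ancestries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating type 1 diabetes genetic risk scores across ancestries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(grsxpop)
```

## The problem

A genetic risk score (GRS) collapses an individual's disease-associated
genetic variation into one number, usually a weighted sum of effect-allele
dosages with weights estimated by GWAS. Type 1 diabetes (T1D) is unusually
well suited to genetic risk scoring because a handful of HLA class II
DR-DQ haplotypes carry very large effects, including strongly non-additive
diplotype effects (most famously DR3/DR4-DQ8 heterozygosity).

Because the underlying GWAS are predominantly European, two questions
matter for any clinical or research use outside European-ancestry groups:

1. **Discrimination.** Does the score still separate cases from controls
   (measured by the area under the ROC curve, AUC) in other populations?
2. **Calibration of thresholds.** Even when discrimination is preserved,
   allele-frequency differences shift the whole score distribution between
   populations. A risk threshold tuned in one population then classifies
   very differently in another, and case/control sets that mix ancestries
   produce misleading AUCs.

`grsxpop` implements the full evaluation workflow for three published
styles of T1D GRS, plus a synthetic multi-population generator so every
stage runs and is testable without access to restricted cohort genotypes.

## Score models

A score definition (`grs_definition`) carries a variant table, an optional
haplotype-tag map and interaction table, and an optional two-SNP
combination rule. Three structures are supported:

* **67-SNP style ("GRS2")** — 14 SNPs tag DR-DQ haplotypes. Each
  individual's diplotype is called from the tag dosages
  (`call_drdq_diplotype`) and scored through an 18-entry unordered-pair
  interaction table; pairs not in the table, and any pair involving an
  untagged (`OTHER`) haplotype, contribute 0. The remaining 53 SNPs (21
  HLA, 32 non-HLA) enter a weighted linear sum. `split_hla_nonhla()`
  decomposes the total into a 35-SNP HLA part (tags + other HLA) and a
  32-SNP non-HLA part.
* **30-SNP style ("GRS1")** — 28 SNPs in a linear sum plus two SNPs that
  jointly tag DR3/DR4-DQ8 carriage through a 9-cell lookup on their
  hard-called genotypes. The rule is data (a companion file), not code.
* **7-SNP style ("AAGRS")** — a pure weighted sum, anchored on two strong
  HLA SNPs (rs2187668, rs9273363).

The packaged `grs1`/`grs2`/`aagrs` fixtures are **synthetic stand-ins**:
they reproduce the published *compositions* exactly (30 = 28 + 2;
67 = 14 + 21 + 32 with 18 interaction pairs; 7 = 5 HLA + 2 non-HLA) with
realistic log-odds magnitudes, but the weights are not transcriptions of
the published supplementary tables, which are not redistributed here. The
definition-file format (`load_grs_definition`) accepts real weight tables
whenever the user has them. The three fixtures deliberately share one
variant panel (the 7-SNP and 30-SNP fixtures draw their variants from the
67-SNP panel), so all three scores can be computed from a single
simulated genotype matrix, as needed for head-to-head comparisons.

### Diplotype calling

Published tag-SNP scores assume imputed dosages close to hard calls. The
caller rounds each tag dosage to the nearest integer in {0, 1, 2}
(dosages farther than `hard_call_threshold`, default 0.5, from every
integer are still rounded but flagged as ambiguous), then assigns
haplotype copies greedily by descending rounded dosage — ties broken by
the raw dosage, then tag order — until two copies are placed; unfilled
slots become `OTHER`. If rounded dosages sum to more than two copies, the
two largest raw dosages win and the row is flagged, never an error. This
greedy hard-call rule is this package's documented choice; the original
publications do not restate their assignment procedure, and no claim is
made that it matches theirs beyond the unambiguous (hard-call) case,
where any sane rule coincides.

### Missing dosages

The default policy is `mean_impute` (substitute the within-cohort mean
dosage of the variant), which preserves the ranking of complete samples
and mirrors how imputation failures are handled in practice; `zero` and
`fail` are available, and every `score()` result carries a per-variant
missingness report.

## Discrimination machinery

* `auc()` is the Mann–Whitney estimator with half credit for ties,
  computed with midranks in O(n log n).
* `bootstrap_auc_ci()` is a *stratified* percentile bootstrap (cases and
  controls resampled separately, sizes preserved; default 2000
  replicates, seeded). The source studies report "95% uncertainties"
  without naming a method; the stratified percentile bootstrap is the
  distribution-free default choice.
* `compare_auc_paired()` combines a paired bootstrap interval for the AUC
  difference with DeLong's test for correlated ROC curves (implemented
  from the placement-value decomposition; the test suite cross-checks it
  against pROC).
* `sens_spec_curve()` / `threshold_report()` implement the
  threshold-transfer analysis: high risk is `score >= t` (the closed-on-
  the-high-side convention), sensitivity is evaluated per population on a
  shared threshold grid.

## Population-mismatch analyses

`crosspop_delta_matrix()` computes AUC(cases of population i vs controls
of population j) for every ordered pair and subtracts an "expected" AUC.
The default convention (`case_population`) takes the expected value for
cell (i, j) to be the within-population AUC of the *case* population i,
because the anchoring description — the AUC each population would achieve
compared with itself — is singular and row-anchored; a `mean_within`
convention (mean of the two within-population AUCs) is available by
argument, and matched cells are exactly zero under both.

`mixed_control_auc()` evaluates one population's cases against pooled
controls, undersampling every included control population without
replacement to the size of the smallest so each carries equal weight. One
seeded draw is the default (the analysis this emulates describes a single
undersampled comparison); `redraws = N` averages over independent draws.

## The synthetic generator

`simulate_population()` draws genotypes haplotype-first: each individual
receives two DR-DQ haplotypes from the scenario's haplotype frequencies,
and each tag SNP's dosage equals the copies of its haplotype — so tag
dosages are hard calls whose sum never exceeds 2, by construction. All
other variants are independent Binomial(2, f) draws. The latent liability
is the definition's own score of the simulated genotype plus a logistic
intercept (by default placed so the baseline prevalence is 10%); case
status is Bernoulli(logistic(liability)), and batches are drawn until the
case and control quotas fill. Making the evaluated score the generating
(Bayes-optimal linear) score means target AUCs can be designed through
the Gaussian closed form AUC ≈ Φ(σ/√2), with σ the population score
standard deviation.

`default_five_population_suite()` bundles five scenarios named for the
cohort structure they emulate — `uganda` (80/2500), `cameroon` (64/2501),
`us_african` (194/235), `us_european` (1109/125, exercising heavy case
imbalance) and `us_hispanic` (266/170). The packaged per-population
frequency tables move effect-allele and risk-haplotype frequencies down
(on the logit scale, in the direction of each variant's weight) for the
African-ancestry-like scenarios and up for the European-like one. These
choices were fixed once, against the analytic closed form, so that the
generating 67-SNP score attains within-population AUCs of roughly
0.80–0.87 — the high-discrimination band reported for these scores — while
control score distributions sit about 2.3 points lower in the
African-like groups. That single design yields, as emergent properties,
the threshold-transfer pattern (lower sensitivity and higher specificity
in low-shifted populations at any shared threshold) and the
population-mismatch sign pattern (positive AUC inflation for high-shifted
cases against low-shifted controls, and vice versa).

### What the generator does and does not emulate

It reproduces the *statistical* structure the analyses rely on:
population-specific allele and haplotype frequencies, non-additive DR-DQ
diplotype risk, case-control sampling with realistic group sizes and
imbalance, and optional completely-at-random missingness and
copula-based dosage correlation. It does **not** model linkage
disequilibrium by default, admixture, imputation error structure, or
haplotype main effects outside the 18 interaction pairs. That last
simplification matters: because DR-DQ risk enters only through named
diplotype pairs, a tag SNP's *marginal* (dosage-linear) information is
diluted relative to real cohorts, so the few-SNP scores (the 7-SNP and
30-SNP fixtures) reach within-population AUCs of only about 0.6–0.74 on
the suite rather than the ~0.8–0.87 reported on real data. Passing tests
therefore demonstrate correctness of the machinery and the direction of
every cross-ancestry effect, not real-data performance levels of any
particular score.

## Numerical and design choices

* Ties in the AUC get 0.5 credit (Mann–Whitney convention); AUC is
  invariant under strictly increasing transforms, which the suite asserts.
* Bootstrap intervals require at least 200 replicates; degenerate
  resamples are handled by the tie-aware estimator.
* `optimal_weighted_sum()` z-scores both inputs and scans the mixing
  weight on a grid (default step 0.01), reporting the in-sample optimum
  — flagged as in-sample, with optional K-fold cross-validation — and
  breaking ties toward 0.5 so identical inputs return an even blend.
* Variant matching against VCFs is by chromosome and position with the
  allele pair deciding orientation; rsIDs are only cross-checked with a
  warning, since they drift across builds. Strand-ambiguous (A/T, C/G)
  variants matching neither orientation are set missing with a warning.
* SNP importance is the per-population difference in mean weighted dosage
  between cases and controls, averaged over populations with equal
  weight (cohort sizes differ by design, and size-weighting would let the
  large control pools dominate); a variant is flagged when the average or
  any single population's difference exceeds 0.1. Tag SNPs have no
  individual linear weight, so their contribution is reported as one
  combined interaction row when requested.
* All randomness (simulation, bootstraps, undersampling, fold splits) is
  seeded explicitly, and the pipeline manifest records the seeds, so any
  run is reproducible byte for byte.

## Problem sizes

The test suite and the acceptance script run the full five-population
suite (about 7,500 individuals over 67 variants), 200-replicate coverage
simulations at n = 500/500, closed-form AUC checks at n = 20,000/20,000,
and exhaustive 7-SNP subset enumeration — sizes chosen to make Monte-Carlo
tolerances tight while keeping a complete run in the order of seconds to
a couple of minutes on one CPU.

## Limitations

* The packaged weights are synthetic; conclusions about the *published*
  scores require the published weight tables, which the definition-file
  format accepts but this package does not redistribute.
* The expected-AUC convention for mismatch matrices cannot be verified
  against the original cohort data; both plausible conventions are
  implemented.
* In-sample optimal weighting biases the combined AUC upward; use the
  cross-validation option when comparing combined against single scores.
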