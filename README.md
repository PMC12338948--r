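# grsxpop — cross-ancestry evaluation of type 1 diabetes genetic risk scores

Genetic risk scores (GRSs) for type 1 diabetes (T1D) discriminate cases
from controls extremely well, because a few HLA class II DR-DQ haplotypes
— and their non-additive diplotype combinations such as DR3/DR4-DQ8 —
carry very large effects. But the GWAS behind these scores are mostly
European, and two things can break when a score travels to another
ancestry group:

* the score distribution shifts with allele frequencies, so a **risk
  threshold** tuned in one population misclassifies in another even when
  discrimination is intact, and
* mixing ancestries between the case and control sets **distorts the
  apparent AUC** of the score.

`grsxpop` is an R package for quantifying both effects. It is aimed at
statistical geneticists and T1D researchers who want to score cohorts
with published T1D GRSs and examine how those scores transfer across
populations.

## What it computes

**Scoring engine** for three published styles of T1D GRS:

* a 67-SNP score in which 14 SNPs tag DR-DQ haplotypes: each individual's
  diplotype is called from tag dosages and scored through an 18-pair
  interaction table, with the remaining 53 SNPs (21 HLA + 32 non-HLA) in
  a weighted linear sum

  `GRS = w_interaction(hap1, hap2) + Σ_s w_s · d_s`

* a 30-SNP score: a 28-SNP linear sum plus a two-SNP DR3/DR4-DQ8
  combination lookup, and
* a 7-SNP African-ancestry-derived score (pure weighted sum).

**Evaluation machinery**: Mann–Whitney AUC with stratified bootstrap 95%
intervals and DeLong paired comparisons; per-population
sensitivity/specificity against shared threshold grids; cross-population
AUC mismatch matrices (AUC of population *i*'s cases vs population *j*'s
controls, minus the matched within-population expectation);
mixed-control AUCs with equalizing undersampling; score combination
(summed, AUC-optimal weighted, SNP-subset augmentation); per-SNP
importance (case-control differences in mean weighted dosage) and allele
frequency/correlation tables.

**Synthetic data**: a haplotype-first case-control generator and a
built-in five-population suite (Uganda-, Cameroon-, US-African-,
US-European- and US-Hispanic-like scenarios) whose frequency design
reproduces the qualitative cross-ancestry structure: lower score
distributions in African-ancestry-like groups with high discrimination
preserved everywhere.

The packaged `grs1`/`grs2`/`aagrs` definitions are **synthetic
stand-ins** that reproduce the published score *compositions* exactly but
not the published weights; real weight tables can be supplied through the
same tab-separated definition format (`load_grs_definition()`).

## Worked example

```r
library(grsxpop)

grs2  <- grs_fixture("grs2")
suite <- default_five_population_suite(grs2, seed = 1)
cohort <- bind_populations(suite)
res <- score(cohort$genotypes, grs2)

# discrimination on the combined African cohort (Uganda + Cameroon)
sel <- cohort$samples$population %in% c("uganda", "cameroon")
roc_result(res$total[sel], cohort$samples$status[sel], n_reps = 2000, seed = 1)
#> <roc_result> AUC 0.836 (0.801-0.867), 144 cases / 5001 controls

# what happens if cases and controls come from different populations?
crosspop_delta_matrix(setNames(res$total, res$sample_id), cohort$samples)
#> <auc_delta_matrix> (case_population convention) delta = raw - expected:
#>             uganda cameroon us_african us_european us_hispanic
#> uganda        0.00    -0.03      -0.11       -0.42       -0.29
#> cameroon      0.03     0.00      -0.08       -0.40       -0.26
#> us_african    0.09     0.07       0.00       -0.30       -0.17
#> us_european   0.13     0.12       0.11        0.00        0.06
#> us_hispanic   0.13     0.12       0.09       -0.09        0.00

# one shared risk threshold, five different operating points
thr <- median(res$total)
threshold_report(res$total, cohort$samples$status,
                 cohort$samples$population, thr)[, 1:3]
#>    population sensitivity specificity
#> 1      uganda       0.850       0.715
#> 2    cameroon       0.859       0.646
#> 3  us_african       0.871       0.468
#> 4 us_european       0.996       0.096
#> 5 us_hispanic       0.970       0.218
```

Read the three tables together: within every population the score
discriminates well (AUC ≈ 0.80–0.87), but African-ancestry-like cases
scored against European-like controls look up to 0.42 AUC points *worse*
than the matched comparison (negative cells), European-like cases against
African-like controls up to 0.13 points *better* (positive cells), and a
single shared threshold gives the African-like groups markedly lower
sensitivity and higher specificity than the European-like group. Those
are exactly the failure modes that make population-matched controls and
population-specific thresholds necessary.

A full pipeline run (simulate → score → evaluate → crosspop →
mixed-controls → combine → importance) with per-stage TSV/JSON outputs
and a reproducibility manifest:

```r
run_pipeline(list(out_dir = "run1", grs = c("grs2", "aagrs", "grs1"),
                  seed = 1, mixed_case_pop = "cameroon"))
```

or from a shell, `Rscript inst/scripts/grsxpop.R run --grs grs2,aagrs --seed 1 --out run1`.

The methods vignette
(`vignettes/cross-ancestry-grs-evaluation.Rmd`) documents the score
models, the diplotype-calling rule, every statistical convention, and
what the synthetic generator does and does not emulate.

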