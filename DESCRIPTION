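Package: grsxpop
Title: Cross-Ancestry Evaluation of Type 1 Diabetes Genetic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes type 1 diabetes genetic risk scores (a 30-SNP score
    with a DR3/DR4-DQ8 combination rule, a 67-SNP score with HLA DR-DQ
    diplotype interaction terms, and a 7-SNP African-ancestry score) from
    genotype dosages, and evaluates their portability across ancestry
    groups: ROC/AUC with stratified bootstrap uncertainty and DeLong
    comparisons, threshold-transfer sensitivity/specificity analysis,
    cross-population AUC mismatch matrices, mixed-control undersampling
    comparisons, score combination, and per-SNP importance statistics.
    Includes a multi-population case-control genotype simulator so the
    full pipeline runs without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
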