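# Shared in-code fixtures and independent oracles.

# Small tagged definition built in code (mirrors the packaged toy but is
# independent of the extdata files).
make_toy_spec <- function() {
  variants <- data.frame(
    variant_id = paste0("rs", 1:9),
    chrom = c("6", "6", "6", "6", "6", "1", "2", "3", "4"),
    pos = c(100, 200, 300, 1000, 2000, 500, 600, 700, 800),
    effect_allele = c("A", "C", "G", "T", "A", "C", "G", "T", "A"),
    other_allele = c("G", "T", "A", "C", "G", "T", "A", "C", "G"),
    weight = c(0, 0, 0, 0.8, -0.5, 0.6, 0.3, -0.2, 0.4),
    region = c(rep("hla_tag", 3), rep("hla_other", 2), rep("non_hla", 4)),
    role = c(rep("haplotype_tag", 3), rep("linear", 6)),
    haplotype_name = c("H1", "H2", "H3", rep(NA, 6)),
    stringsAsFactors = FALSE)
  interactions <- data.frame(hap_a = c("H1", "H1", "H3"),
                             hap_b = c("H1", "H2", "H3"),
                             weight = c(2.0, 1.2, -1.0))
  grs_definition(variants, interactions = interactions)
}

# Pure linear definition with k variants of given weights.
make_linear_spec <- function(weights, region = "non_hla") {
  k <- length(weights)
  grs_definition(data.frame(
    variant_id = sprintf("rsL%03d", seq_len(k)),
    chrom = "1", pos = seq_len(k) * 1000,
    effect_allele = "A", other_allele = "G",
    weight = weights, region = region, role = "linear",
    haplotype_name = NA, stringsAsFactors = FALSE))
}

# Random hard-call genotype matrix for a definition.
random_genotypes <- function(spec, n, seed = 1, freq = 0.4) {
  withr::with_seed(seed, {
    k <- nrow(spec$variants)
    genotype_matrix(
      matrix(stats::rbinom(n * k, 2, freq), n, k),
      sample_ids = sprintf("s%04d", seq_len(n)),
      variant_ids = spec$variants$variant_id)
  })
}

# Brute-force AUC: count concordant pairs one by one.
auc_brute <- function(scores, case) {
  x <- scores[case]; y <- scores[!case]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(x) * length(y))
}

# Brute-force linear score: per-sample loop-and-sum.
linear_brute <- function(dosages, weights) {
  out <- numeric(nrow(dosages))
  for (i in seq_len(nrow(dosages))) {
    s <- 0
    for (j in seq_len(ncol(dosages))) s <- s + weights[j] * dosages[i, j]
    out[i] <- s
  }
  out
}

# Two-population shifted-Gaussian score/sample set: population B's case and
# control distributions both sit `shift` below population A's.
shifted_gaussian_cohort <- function(n_case = 300, n_ctrl = 300, sep = 1.5,
                                    shift = 2, seed = 1) {
  withr::with_seed(seed, {
    sc <- c(stats::rnorm(n_case, sep), stats::rnorm(n_ctrl, 0),
            stats::rnorm(n_case, sep - shift), stats::rnorm(n_ctrl, -shift))
    ids <- sprintf("p%05d", seq_along(sc))
    samples <- sample_table(
      ids,
      rep(c("popA", "popB"), each = n_case + n_ctrl),
      rep(c(rep("T1D", n_case), rep("non_T1D", n_ctrl)), 2))
    list(scores = stats::setNames(sc, ids), samples = samples)
  })
}
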