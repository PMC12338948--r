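#' Population scenario for the case-control genotype simulator
#'
#' Describes one population to simulate: target case/control counts,
#' control-population effect-allele frequencies for every linear (and
#' combination) variant, DR-DQ haplotype frequencies (including `OTHER`,
#' summing to 1), optional true effect sizes (defaulting to the score's own
#' weights, which makes the evaluated score the Bayes-optimal linear
#' classifier of the simulated data), and the logistic prevalence
#' intercept.
#'
#' @param name population label.
#' @param n_cases,n_controls positive target counts.
#' @param allele_freqs named numeric vector in (0, 1): effect-allele
#'   frequency per non-tag variant.
#' @param haplotype_freqs named numeric vector over the tagged haplotypes
#'   plus `OTHER`, summing to 1 (required only for definitions with tags).
#' @param effect_sizes optional list with elements `linear` (named vector
#'   replacing linear weights in the liability) and/or `interaction_scale`
#'   (scalar multiplier on the interaction/combination term); used to
#'   decouple the generating effects from the evaluated score.
#' @param prevalence_intercept logistic intercept added to the liability;
#'   `NULL` (default) sets it so the baseline population prevalence is
#'   `target_prevalence`.
#' @param target_prevalence baseline disease prevalence used when
#'   `prevalence_intercept` is `NULL` (default 0.1).
#' @return List of class `population_scenario`.
#' @export
population_scenario <- function(name, n_cases, n_controls, allele_freqs,
                                haplotype_freqs = NULL, effect_sizes = NULL,
                                prevalence_intercept = NULL,
                                target_prevalence = 0.1) {
  if (n_cases < 1 || n_controls < 1) stopf("counts must be positive")
  if (is.null(names(allele_freqs)) || any(!nzchar(names(allele_freqs)))) {
    stopf("allele_freqs must be named by variant id")
  }
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    stopf("allele frequencies must lie strictly in (0, 1)")
  }
  if (!is.null(haplotype_freqs)) {
    if (!"OTHER" %in% names(haplotype_freqs)) {
      stopf("haplotype_freqs must include an OTHER entry")
    }
    if (abs(sum(haplotype_freqs) - 1) > 1e-9) {
      stopf("haplotype_freqs must sum to 1 (got %.12f)", sum(haplotype_freqs))
    }
    if (any(haplotype_freqs < 0)) stopf("haplotype frequencies must be >= 0")
  }
  structure(list(name = name, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 allele_freqs = allele_freqs,
                 haplotype_freqs = haplotype_freqs,
                 effect_sizes = effect_sizes,
                 prevalence_intercept = prevalence_intercept,
                 target_prevalence = target_prevalence),
            class = "population_scenario")
}

# Expected population-mean score under a scenario (used to centre the
# logistic intercept at the requested baseline prevalence).
expected_score_mean <- function(spec, scenario) {
  v <- spec$variants
  lin <- v[v$role == "linear", , drop = FALSE]
  f <- scenario$allele_freqs[lin$variant_id]
  mu <- sum(lin$weight * 2 * f)
  hf <- scenario$haplotype_freqs
  if (!is.null(hf) && nrow(spec$interactions)) {
    it <- spec$interactions
    p_pair <- ifelse(it$hap_a == it$hap_b,
                     hf[it$hap_a]^2,
                     2 * hf[it$hap_a] * hf[it$hap_b])
    mu <- mu + sum(it$weight * p_pair)
  }
  mu
}

#' Simulate one case-control population
#'
#' Genotypes are drawn haplotype-first: each individual receives two DR-DQ
#' haplotypes from `haplotype_freqs`, and each tag SNP's dosage is the
#' number of copies of its haplotype (so tag dosages are hard calls and sum
#' to at most 2 by construction). Every other variant's dosage is an
#' independent `Binomial(2, f)` draw. The latent liability is the
#' definition's own score of the simulated genotype (optionally with
#' overridden effect sizes) plus the prevalence intercept; disease status
#' is `Bernoulli(logistic(liability))`, and sampling continues in batches
#' until both the case and control quotas are filled.
#'
#' @param scenario a [population_scenario()].
#' @param spec a [grs_definition()].
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @param max_batches attempt cap before declaring the quotas infeasible.
#' @return List of class `simulated_population`: `genotypes` (a
#'   [genotype_matrix()] over all of `spec`'s variants), `samples` (a
#'   [sample_table()]), and `true_diplotypes` (data.frame `sample_id`,
#'   `hap1`, `hap2` of the generating haplotypes, when tags exist).
#' @export
simulate_population <- function(scenario, spec, seed, max_batches = 60) {
  stopifnot(inherits(scenario, "population_scenario"),
            inherits(spec, "grs_definition"))
  v <- spec$variants
  tag <- v$role == "haplotype_tag"
  non_tag_ids <- v$variant_id[!tag]
  f <- scenario$allele_freqs[non_tag_ids]
  if (anyNA(f)) {
    stopf("scenario lacks allele frequencies for: %s",
          paste(non_tag_ids[is.na(f)], collapse = ", "))
  }
  hf <- scenario$haplotype_freqs
  if (any(tag) && is.null(hf)) {
    stopf("definition has haplotype tags but the scenario has no haplotype_freqs")
  }
  tags <- haplotype_tags(spec)

  liab_spec <- liability_spec(spec, scenario)
  intercept <- scenario$prevalence_intercept %||%
    (stats::qlogis(scenario$target_prevalence) -
       expected_score_mean(liab_spec, scenario))

  with_seed(seed, {
    need_c <- scenario$n_cases; need_k <- scenario$n_controls
    # rough acceptance-rate guess just to size batches
    p0 <- min(max(scenario$target_prevalence, 0.01), 0.5)
    acc_case <- list(); acc_ctrl <- list()
    got_c <- 0L; got_k <- 0L
    for (b in seq_len(max_batches)) {
      n <- min(200000L,
               max(1000L,
                   as.integer(2 * max((need_c - got_c) / p0,
                                      (need_k - got_k) / (1 - p0)))))
      m <- matrix(0, n, nrow(v), dimnames = list(NULL, v$variant_id))
      dip <- NULL
      if (any(tag)) {
        hap_names <- names(hf)
        h1 <- sample(hap_names, n, replace = TRUE, prob = hf)
        h2 <- sample(hap_names, n, replace = TRUE, prob = hf)
        for (hn in names(tags)) {
          m[, tags[[hn]]] <- (h1 == hn) + (h2 == hn)
        }
        dip <- cbind(h1, h2)
      }
      m[, non_tag_ids] <- matrix(
        stats::rbinom(n * length(f), 2L, rep(f, each = n)),
        n, length(f))
      g <- genotype_matrix(m, sample_ids = paste0("tmp", seq_len(n)))
      liab <- score(g, liab_spec, missing_policy = "zero")$total + intercept
      is_case <- stats::rbinom(n, 1L, stats::plogis(liab)) == 1L
      if (got_c < need_c && any(is_case)) {
        take <- which(is_case)[seq_len(min(sum(is_case), need_c - got_c))]
        acc_case[[length(acc_case) + 1L]] <-
          list(m = m[take, , drop = FALSE],
               dip = if (!is.null(dip)) dip[take, , drop = FALSE])
        got_c <- got_c + length(take)
      }
      if (got_k < need_k && any(!is_case)) {
        take <- which(!is_case)[seq_len(min(sum(!is_case), need_k - got_k))]
        acc_ctrl[[length(acc_ctrl) + 1L]] <-
          list(m = m[take, , drop = FALSE],
               dip = if (!is.null(dip)) dip[take, , drop = FALSE])
        got_k <- got_k + length(take)
      }
      if (got_c >= need_c && got_k >= need_k) break
    }
    if (got_c < need_c || got_k < need_k) {
      stopf("could not reach %d cases / %d controls within %d batches (got %d/%d); the scenario is infeasible",
            need_c, need_k, max_batches, got_c, got_k)
    }
    mm <- rbind(do.call(rbind, lapply(acc_case, `[[`, "m")),
                do.call(rbind, lapply(acc_ctrl, `[[`, "m")))
    ids <- sprintf("%s_%05d", scenario$name, seq_len(nrow(mm)))
    status <- c(rep("T1D", need_c), rep("non_T1D", need_k))
    out <- list(
      genotypes = genotype_matrix(mm, sample_ids = ids),
      samples = sample_table(ids, rep(scenario$name, nrow(mm)), status),
      scenario = scenario$name)
    if (any(tag)) {
      dd <- rbind(do.call(rbind, lapply(acc_case, `[[`, "dip")),
                  do.call(rbind, lapply(acc_ctrl, `[[`, "dip")))
      out$true_diplotypes <- data.frame(sample_id = ids, hap1 = dd[, 1],
                                        hap2 = dd[, 2],
                                        stringsAsFactors = FALSE)
    }
    class(out) <- "simulated_population"
    out
  })
}

# Definition used for the liability: optionally swaps in scenario effect
# sizes while keeping the variant structure.
liability_spec <- function(spec, scenario) {
  es <- scenario$effect_sizes
  if (is.null(es)) return(spec)
  v <- spec$variants
  if (!is.null(es$linear)) {
    i <- match(names(es$linear), v$variant_id)
    if (anyNA(i)) stopf("effect_sizes$linear names unknown variants")
    v$weight[i] <- unname(es$linear)
  }
  it <- spec$interactions
  cb <- spec$combinations
  if (!is.null(es$interaction_scale)) {
    if (nrow(it)) it$weight <- it$weight * es$interaction_scale
    if (!is.null(cb)) cb$weight <- cb$weight * es$interaction_scale
  }
  grs_definition(v, interactions = if (nrow(it)) it else NULL,
                 combinations = cb, name = "custom")
}

#' @export
print.simulated_population <- function(x, ...) {
  tab <- table(x$samples$status)
  cat(sprintf("<simulated_population> %s: %d cases / %d controls, %d variants\n",
              x$scenario, tab[["T1D"]], tab[["non_T1D"]],
              length(x$genotypes$variant_ids)))
  invisible(x)
}

#' Built-in five-population study scenarios
#'
#' Returns the five default [population_scenario()]s (`uganda`, `cameroon`,
#' `us_african`, `us_european`, `us_hispanic`) for the packaged 67-SNP
#' definition. Per-population effect-allele and DR-DQ haplotype frequencies
#' are read from the packaged tables
#' (`five_pop_allele_freqs_synthetic.tsv`,
#' `five_pop_haplotype_freqs_synthetic.tsv`); African-ancestry-like
#' populations carry lower risk-allele and risk-haplotype frequencies, so
#' their score distributions sit systematically lower while every
#' within-population AUC stays in the high-discrimination band. Cohort
#' sizes mirror the study structure, including the heavily case-skewed
#' European-like group (1109/125) and the large African population control
#' pools (144 cases vs 5001 controls combined).
#'
#' @param spec definition whose non-tag variants the frequency tables must
#'   cover; defaults to `grs_fixture("grs2")`.
#' @return Named list of five [population_scenario()]s.
#' @export
default_five_population_scenarios <- function(spec = grs_fixture("grs2")) {
  path <- function(f) system.file("extdata", f, package = "grsxpop",
                                  mustWork = TRUE)
  af <- utils::read.delim(path("five_pop_allele_freqs_synthetic.tsv"),
                          stringsAsFactors = FALSE)
  hf <- utils::read.delim(path("five_pop_haplotype_freqs_synthetic.tsv"),
                          stringsAsFactors = FALSE)
  sizes <- list(uganda = c(80L, 2500L), cameroon = c(64L, 2501L),
                us_african = c(194L, 235L), us_european = c(1109L, 125L),
                us_hispanic = c(266L, 170L))
  pops <- names(sizes)
  v <- spec$variants
  non_tag <- v$variant_id[v$role != "haplotype_tag"]
  missing <- setdiff(non_tag, af$variant_id)
  if (length(missing)) {
    stopf("frequency table lacks variant(s) of this definition: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  out <- lapply(pops, function(p) {
    freqs <- stats::setNames(af[[p]], af$variant_id)[non_tag]
    haps <- stats::setNames(hf[[p]], hf$haplotype)
    population_scenario(p, sizes[[p]][1], sizes[[p]][2],
                        allele_freqs = freqs,
                        haplotype_freqs = if (any(v$role == "haplotype_tag")) haps)
  })
  stats::setNames(out, pops)
}

#' Simulate the built-in five-population suite
#'
#' Runs [simulate_population()] for each of the five default scenarios with
#' sub-seeds derived from `seed`.
#'
#' @inheritParams default_five_population_scenarios
#' @param seed master integer seed.
#' @param missing_rate optional completely-at-random dosage masking rate
#'   in \[0, 1).
#' @return Named list of `simulated_population` objects.
#' @export
default_five_population_suite <- function(spec = grs_fixture("grs2"), seed = 1,
                                          missing_rate = 0) {
  scenarios <- default_five_population_scenarios(spec)
  seeds <- derive_seeds(seed, length(scenarios))
  out <- Map(function(sc, s) {
    sim <- simulate_population(sc, spec, seed = s)
    if (missing_rate > 0) {
      sim$genotypes <- mask_dosages(sim$genotypes, missing_rate,
                                    seed = (s + 1L) %% .Machine$integer.max)
    }
    sim
  }, scenarios, as.list(seeds))
  stats::setNames(out, names(scenarios))
}

#' Mask dosages completely at random
#' @param g a [genotype_matrix()].
#' @param rate masking probability per entry, in \[0, 1).
#' @param seed integer seed.
#' @return The masked [genotype_matrix()].
#' @export
mask_dosages <- function(g, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  d <- g$dosages
  mask <- with_seed(seed, stats::runif(length(d)) < rate)
  d[mask] <- NA_real_
  genotype_matrix(d)
}

#' Stack simulated populations into one dataset
#'
#' @param suite list of `simulated_population` objects sharing a variant
#'   panel.
#' @return List: `genotypes` (row-bound [genotype_matrix()]), `samples`
#'   (row-bound [sample_table()]).
#' @export
bind_populations <- function(suite) {
  g <- do.call(rbind, lapply(suite, function(s) s$genotypes$dosages))
  st <- do.call(rbind, lapply(suite, function(s) as.data.frame(s$samples)))
  list(genotypes = genotype_matrix(g),
       samples = sample_table(st$sample_id, st$population, st$status))
}

#' Correlated dosage sampler (Gaussian copula)
#'
#' Draws per-variant dosages whose pairwise allele-level correlation
#' follows `corr` via a Gaussian copula on the two allele draws; used to
#' exercise linkage-disequilibrium-aware statistics. Diagonal must be 1.
#'
#' @param n number of individuals.
#' @param freqs named effect-allele frequencies in (0, 1).
#' @param corr positive-semidefinite correlation matrix over the variants.
#' @param seed integer seed.
#' @return A [genotype_matrix()] of hard-call dosages.
#' @export
simulate_ld_block <- function(n, freqs, corr, seed = 1) {
  k <- length(freqs)
  stopifnot(nrow(corr) == k, ncol(corr) == k)
  ch <- chol(corr)
  with_seed(seed, {
    d <- matrix(0, n, k)
    for (allele in 1:2) {
      z <- matrix(stats::rnorm(n * k), n, k) %*% ch
      u <- stats::pnorm(z)
      d <- d + (u < matrix(freqs, n, k, byrow = TRUE))
    }
    genotype_matrix(d, sample_ids = paste0("s", seq_len(n)),
                    variant_ids = names(freqs))
  })
}
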