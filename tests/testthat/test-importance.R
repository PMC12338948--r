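make_imp_cohort <- function(spec, n_per_group = 200, seed = 151,
                            pops = c("p1", "p2")) {
  withr::with_seed(seed, {
    k <- nrow(spec$variants)
    n <- n_per_group * 2 * length(pops)
    g <- genotype_matrix(matrix(rbinom(n * k, 2, 0.4), n, k),
                         sample_ids = sprintf("i%05d", 1:n),
                         variant_ids = spec$variants$variant_id)
    st <- sample_table(g$sample_ids,
                       rep(pops, each = 2 * n_per_group),
                       rep(c(rep("T1D", n_per_group),
                             rep("non_T1D", n_per_group)), length(pops)))
    list(g = g, samples = st)
  })
}

test_that("importance deltas follow the weighted-dosage arithmetic", {
  # one variant, w = 0.5, case mean dosage 1.4 vs control 1.0 -> 0.2, flagged
  spec <- make_linear_spec(0.5)
  d <- matrix(c(rep(c(1, 2), c(3, 2)), rep(1, 5)), ncol = 1)
  g <- genotype_matrix(d, sample_ids = paste0("s", 1:10),
                       variant_ids = "rsL001")
  st <- sample_table(g$sample_ids, rep("p1", 10),
                     rep(c("T1D", "non_T1D"), each = 5))
  imp <- snp_importance(g, spec, st)
  expect_equal(imp$average_delta, 0.5 * (1.4 - 1.0), tolerance = 1e-12)
  expect_true(imp$flagged)

  # equal means -> zero delta, not flagged
  g2 <- genotype_matrix(matrix(1, 10, 1), sample_ids = paste0("s", 1:10),
                        variant_ids = "rsL001")
  imp2 <- snp_importance(g2, spec, st)
  expect_equal(imp2$average_delta, 0)
  expect_false(imp2$flagged)
})

test_that("summed per-variant deltas equal the mean linear-score gap", {
  spec <- make_linear_spec(c(0.7, -0.4, 0.3, 0.2))
  ch <- make_imp_cohort(spec, pops = "p1")
  imp <- snp_importance(ch$g, spec, ch$samples)
  lin <- linear_component(ch$g, spec)
  case <- ch$samples$status == "T1D"
  gap <- mean(lin[case]) - mean(lin[!case])
  expect_equal(sum(imp$average_delta), gap, tolerance = 1e-9)
})

test_that("flagging uses both the average and single-population rules", {
  spec <- make_linear_spec(c(1, 1))
  # variant 1: delta 0.15 in p1 only; variant 2: never above 0.1
  d <- rbind(
    matrix(1, 10, 2),                    # p1 cases (overwritten below)
    matrix(1, 10, 2),                    # p1 controls
    matrix(1, 10, 2), matrix(1, 10, 2))  # p2 cases/controls
  d[1:10, 1] <- 1.15; d[1:10, 2] <- 1.05
  d <- pmin(d, 2)
  g <- genotype_matrix(d, sample_ids = sprintf("s%02d", 1:40),
                       variant_ids = spec$variants$variant_id)
  st <- sample_table(g$sample_ids, rep(c("p1", "p2"), each = 20),
                     rep(c(rep("T1D", 10), rep("non_T1D", 10)), 2))
  imp <- snp_importance(g, spec, st)
  v1 <- imp[imp$variant_id == "rsL001", ]
  v2 <- imp[imp$variant_id == "rsL002", ]
  expect_equal(v1$delta_p1, 0.15, tolerance = 1e-12)
  expect_equal(v1$average_delta, 0.075, tolerance = 1e-12)
  expect_true(v1$flagged)     # single-population rule
  expect_false(v2$flagged)
})

test_that("populations lacking a class are dropped with a warning", {
  spec <- make_linear_spec(c(0.5, 0.3))
  ch <- make_imp_cohort(spec, seed = 157)
  st <- ch$samples
  st$status[st$population == "p2"] <- "non_T1D"
  expect_warning(imp <- snp_importance(ch$g, spec, st), "lacks a class")
  expect_true(all(is.na(imp$delta_p2)))
  expect_false(anyNA(imp$average_delta))
})

test_that("importance ranking recovers designed effect sizes", {
  k <- 12
  true_w <- seq(1.2, 0.1, length.out = k)
  spec <- make_linear_spec(rep(1, k))   # unit weights: delta tracks dosage gap
  withr::with_seed(163, {
    n <- 4000
    g <- genotype_matrix(matrix(rbinom(n * k, 2, 0.4), n, k),
                         sample_ids = sprintf("r%05d", 1:n),
                         variant_ids = spec$variants$variant_id)
    liab <- drop(g$dosages %*% true_w)
    case <- rbinom(n, 1, plogis(liab - mean(liab))) == 1
    # keep 2000/2000
    st <- sample_table(g$sample_ids, rep("p1", n),
                       ifelse(case, "T1D", "non_T1D"))
    imp <- snp_importance(g, spec, st)
    est <- imp$average_delta[match(spec$variants$variant_id, imp$variant_id)]
    rho <- cor(true_w, est, method = "spearman")
    expect_gte(rho, 0.9)
  })
})

test_that("allele frequencies are bounded and recover generating values", {
  spec <- make_linear_spec(c(0.4, -0.3))
  withr::with_seed(167, {
    f_true <- c(0.25, 0.6)
    n <- 1000
    g <- genotype_matrix(
      cbind(rbinom(n, 2, f_true[1]), rbinom(n, 2, f_true[2])),
      sample_ids = sprintf("a%04d", 1:n),
      variant_ids = spec$variants$variant_id)
    st <- sample_table(g$sample_ids, rep("p1", n),
                       rep(c("T1D", "non_T1D"), n / 2))
    tab <- allele_frequency_table(g, spec, st)
    expect_true(all(tab$frequency >= 0 & tab$frequency <= 1))
    for (i in 1:2) {
      sub <- tab[tab$variant_id == spec$variants$variant_id[i], ]
      se <- sqrt(f_true[i] * (1 - f_true[i]) / (2 * n / 2))
      expect_true(all(abs(sub$frequency - f_true[i]) < 3 * se))
    }
    expect_equal(unique(tab$direction[tab$variant_id == "rsL001"]), "risk")
    expect_equal(unique(tab$direction[tab$variant_id == "rsL002"]),
                 "protective")
  })
  # all dosages 2 -> frequency 1
  g2 <- genotype_matrix(matrix(2, 4, 2),
                        sample_ids = paste0("s", 1:4),
                        variant_ids = spec$variants$variant_id)
  st2 <- sample_table(g2$sample_ids, rep("p1", 4),
                      rep(c("T1D", "non_T1D"), 2))
  expect_true(all(allele_frequency_table(g2, spec, st2)$frequency == 1))
})

test_that("cross-correlations recover designed linkage disequilibrium", {
  # haplotype-level simulation with designed D, so the dosage correlation
  # has the closed form r = D / sqrt(pa qa pb qb)
  withr::with_seed(173, {
    n <- 5000
    pa <- 0.3; pb <- 0.4; D <- 0.1
    hap_p <- c(pa * pb + D, pa * (1 - pb) - D,
               (1 - pa) * pb - D, (1 - pa) * (1 - pb) + D)
    draw <- function() {
      h <- sample(1:4, n, replace = TRUE, prob = hap_p)
      cbind(a = as.numeric(h %in% c(1, 2)), b = as.numeric(h %in% c(1, 3)))
    }
    dos <- draw() + draw()
    g <- genotype_matrix(cbind(dos, vI = rbinom(n, 2, 0.5)),
                         sample_ids = sprintf("h%05d", 1:n),
                         variant_ids = c("va", "vb", "vI"))
    m <- snp_cross_correlations(g, c("va", "vI"), c("va", "vb"))
    expect_equal(m["va", "va"], 1)
    r_theory <- D / sqrt(pa * (1 - pa) * pb * (1 - pb))
    se <- (1 - r_theory^2) / sqrt(n)
    expect_lt(abs(m["va", "vb"] - r_theory), 3 * se + 0.01)
    expect_lt(abs(m["vI", "vb"]), 0.05)
  })
})

test_that("the copula LD sampler induces positive dosage correlation", {
  g <- simulate_ld_block(4000, c(v1 = 0.3, v2 = 0.4),
                         rbind(c(1, 0.6), c(0.6, 1)), seed = 174)
  m <- snp_cross_correlations(g, "v1", "v2")
  expect_gt(m[1, 1], 0.3)   # attenuated relative to the latent 0.6
  expect_lt(m[1, 1], 0.6)
})

test_that("zero-variance columns yield NA correlations, not errors", {
  g <- genotype_matrix(cbind(v1 = c(0, 1, 2, 1), v2 = c(1, 1, 1, 1)),
                       sample_ids = paste0("s", 1:4))
  m <- snp_cross_correlations(g, "v1", "v2")
  expect_true(is.na(m[1, 1]))
})
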