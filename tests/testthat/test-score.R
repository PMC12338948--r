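test_that("linear component matches a per-sample loop-and-sum oracle", {
  spec <- make_linear_spec(withr::with_seed(11, round(rnorm(10), 3)))
  g <- random_genotypes(spec, 100, seed = 12)
  got <- linear_component(g, spec)
  want <- linear_brute(g$dosages, spec$variants$weight)
  expect_equal(unname(got), want, tolerance = 1e-12)

  # hand example: weights (0.5, 1.0), dosages (2, 1) -> 2.0
  s2 <- make_linear_spec(c(0.5, 1.0))
  g2 <- genotype_matrix(matrix(c(2, 1), 1, 2,
                               dimnames = list("s1", s2$variants$variant_id)))
  expect_equal(unname(linear_component(g2, s2)), 2.0)
  g0 <- genotype_matrix(matrix(0, 1, 2,
                               dimnames = list("s1", s2$variants$variant_id)))
  expect_equal(unname(linear_component(g0, s2)), 0.0)
})

test_that("missing-dosage policies behave as documented", {
  spec <- make_linear_spec(c(1, 1))
  d <- matrix(c(2, NA, 0, 2), 2, 2,
              dimnames = list(c("s1", "s2"), spec$variants$variant_id))
  g <- genotype_matrix(d)
  expect_error(linear_component(g, spec, missing_policy = "fail"),
               "s2/rsL001")
  expect_equal(unname(linear_component(g, spec, missing_policy = "zero")),
               c(2, 2))
  # mean impute: column mean of rsL001 is 2
  expect_equal(unname(linear_component(g, spec, missing_policy = "mean_impute")),
               c(2, 4))
  # zero-policy monotonicity: masking a positive-weight variant never
  # raises a score
  spec_pos <- make_linear_spec(c(0.7, 0.2, 0.9))
  gp <- random_genotypes(spec_pos, 50, seed = 3)
  base <- linear_component(gp, spec_pos, missing_policy = "zero")
  d2 <- gp$dosages; d2[, 2] <- NA
  masked <- linear_component(genotype_matrix(d2), spec_pos,
                             missing_policy = "zero")
  expect_true(all(masked <= base + 1e-12))
})

test_that("diplotype calling handles forced, homozygous and untagged cases", {
  m <- rbind(s1 = c(H1 = 1, H2 = 1, H3 = 0),
             s2 = c(H1 = 2, H2 = 0, H3 = 0),
             s3 = c(H1 = 0, H2 = 0, H3 = 0),
             s4 = c(H1 = 0, H2 = 1, H3 = 0))
  calls <- call_drdq_diplotype(m)
  expect_equal(sort(c(calls$hap1[1], calls$hap2[1])), c("H1", "H2"))
  expect_equal(c(calls$hap1[2], calls$hap2[2]), c("H1", "H1"))
  expect_equal(c(calls$hap1[3], calls$hap2[3]), c("OTHER", "OTHER"))
  expect_equal(sort(c(calls$hap1[4], calls$hap2[4])), c("H2", "OTHER"))
  expect_false(any(calls$ambiguous))
  expect_false(any(calls$conflict))
})

test_that("conflicting tag dosages keep the two largest without erroring", {
  m <- rbind(s1 = c(H1 = 1.4, H2 = 0.9, H3 = 1.1))
  calls <- call_drdq_diplotype(m)
  expect_true(calls$conflict[1])
  expect_equal(sort(c(calls$hap1[1], calls$hap2[1])), c("H1", "H3"))

  # rounded dosage 2 on one tag plus 1 elsewhere: homozygote wins
  m2 <- rbind(s1 = c(H1 = 1.9, H2 = 1.0, H3 = 0))
  c2 <- call_drdq_diplotype(m2)
  expect_equal(c(c2$hap1[1], c2$hap2[1]), c("H1", "H1"))
})

test_that("ambiguous dosages are rounded but flagged", {
  calls <- call_drdq_diplotype(rbind(s1 = c(H1 = 0.6, H2 = 0, H3 = 0)),
                               hard_call_threshold = 0.3)
  expect_true(calls$ambiguous[1])
  expect_equal(sort(c(calls$hap1[1], calls$hap2[1])), c("H1", "OTHER"))
  expect_error(call_drdq_diplotype(rbind(c(H1 = 1)), hard_call_threshold = 0),
               "\\(0, 0.5\\]")
})

test_that("interaction lookup is symmetric and defaults to zero", {
  spec <- make_toy_spec()
  calls <- data.frame(sample_id = c("a", "b", "c", "d"),
                      hap1 = c("H1", "H2", "OTHER", "H2"),
                      hap2 = c("H2", "H1", "OTHER", "H3"),
                      stringsAsFactors = FALSE)
  w <- interaction_component(calls, spec)
  expect_equal(unname(w), c(1.2, 1.2, 0, 0))
})

test_that("score components always sum to the total", {
  spec <- grs_fixture("grs2")
  sim <- simulate_population(
    default_five_population_scenarios(spec)$us_hispanic, spec, seed = 99)
  r <- score(sim$genotypes, spec)
  expect_lt(max(abs(r$total - (r$interaction + r$hla_linear +
                                 r$non_hla_linear))), 1e-9)
  sp <- split_hla_nonhla(r)
  expect_lt(max(abs(sp$hla_score + sp$non_hla_score - r$total)), 1e-9)
})

test_that("the HLA/non-HLA split is defined only for tagged scores", {
  aa <- grs_fixture("aagrs")
  g <- random_genotypes(aa, 5, seed = 2)
  expect_error(split_hla_nonhla(score(g, aa)), "tagged")
})

test_that("a pure linear score equals linear_component directly", {
  aa <- grs_fixture("aagrs")
  g <- random_genotypes(aa, 60, seed = 8)
  r <- score(g, aa)
  expect_equal(r$total,
               unname(linear_component(g, aa, aa$variants$variant_id[
                 aa$variants$role == "linear"])))
  expect_equal(r$interaction, rep(0, 60))
})

test_that("GRS1 adds the combination lookup to its linear sum", {
  g1 <- grs_fixture("grs1")
  g <- random_genotypes(g1, 40, seed = 21)
  r <- score(g, g1)
  lin <- linear_component(g, g1)
  cb <- g1$combinations
  ids <- g1$variants$variant_id[g1$variants$role == "combination"]
  lut <- setNames(cb$weight, paste(cb$geno_a, cb$geno_b))
  want <- unname(lut[paste(g$dosages[, ids[1]], g$dosages[, ids[2]])])
  expect_equal(r$total, unname(lin) + want)
  expect_equal(r$interaction, want)
})

test_that("scoring a zero genotype with untagged diplotype gives zero", {
  spec <- make_toy_spec()
  g <- genotype_matrix(matrix(0, 1, 9,
                              dimnames = list("s1",
                                              spec$variants$variant_id)))
  r <- score(g, spec)
  expect_equal(r$total, 0)
})

test_that("scores are order-independent across samples and dosage-linear", {
  spec <- grs_fixture("aagrs")
  g <- random_genotypes(spec, 30, seed = 4)
  r_all <- score(g, spec)$total
  g1 <- genotype_matrix(g$dosages[1:10, , drop = FALSE])
  g2 <- genotype_matrix(g$dosages[11:30, , drop = FALSE])
  expect_equal(c(score(g1, spec)$total, score(g2, spec)$total), r_all)
  # dosage linearity on a linear-only score
  half <- genotype_matrix(g$dosages / 2)
  expect_equal(score(half, spec)$total, r_all / 2, tolerance = 1e-12)
})

test_that("permuting the called haplotype pair never changes the score", {
  spec <- make_toy_spec()
  g <- random_genotypes(spec, 80, seed = 31, freq = 0.3)
  r <- score(g, spec)
  calls <- attr(r, "diplotype_calls")
  swapped <- calls
  swapped$hap1 <- calls$hap2; swapped$hap2 <- calls$hap1
  expect_equal(interaction_component(swapped, spec),
               interaction_component(calls, spec))
})
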