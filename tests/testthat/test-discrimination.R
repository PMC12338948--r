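test_that("AUC equals brute-force concordant-pair counting", {
  expect_equal(auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  withr::with_seed(42, {
    for (i in 1:100) {
      n1 <- sample(1:25, 1); n0 <- sample(1:25, 1)
      # integer scores so ties occur
      sc <- sample(1:8, n1 + n0, replace = TRUE)
      case <- c(rep(TRUE, n1), rep(FALSE, n0))
      expect_equal(auc(sc, case), auc_brute(sc, case), tolerance = 1e-12)
    }
  })
})

test_that("AUC input validation and null symmetry hold", {
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "at least one case")
  sc <- withr::with_seed(1, rnorm(40))
  perm <- withr::with_seed(2, {
    vapply(1:2000, function(i) {
      auc(sc, sample(c(rep(TRUE, 20), rep(FALSE, 20))))
    }, numeric(1))
  })
  expect_lt(abs(mean(perm) - 0.5), 3 * sd(perm) / sqrt(2000))
  # complement identity for tie-free scores
  case <- c(rep(TRUE, 20), rep(FALSE, 20))
  expect_equal(auc(sc, case) + auc(-sc, case), 1)
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(3, {
    sc <- rnorm(100); case <- rbinom(100, 1, 0.4) == 1
    case[1] <- TRUE; case[2] <- FALSE
    a0 <- auc(sc, case)
    expect_equal(auc(exp(sc), case), a0)
    expect_equal(auc(5 * sc + 3, case), a0)
    expect_equal(auc(rank(sc), case), a0)
  })
})

test_that("empirical AUC matches the Gaussian closed form", {
  withr::with_seed(7, {
    for (prm in list(c(1, 1, 1), c(1.5, 2, 0.5), c(0.8, 1, 1.5))) {
      mu1 <- prm[1]; s1 <- prm[2]; s0 <- prm[3]
      n <- 20000
      sc <- c(rnorm(n, mu1, s1), rnorm(n, 0, s0))
      case <- c(rep(TRUE, n), rep(FALSE, n))
      expect_equal(auc(sc, case), pnorm(mu1 / sqrt(s1^2 + s0^2)),
                   tolerance = 0.01)
    }
  })
})

test_that("roc_points is monotone and brackets the extremes", {
  withr::with_seed(5, {
    sc <- rnorm(200); case <- c(rep(TRUE, 80), rep(FALSE, 120))
    pts <- roc_points(sc, case)
    expect_true(all(diff(pts$sensitivity) >= 0))   # thresholds descend
    expect_true(all(diff(pts$specificity) <= 0))
    expect_equal(pts$sensitivity[1], 0)
    expect_equal(pts$specificity[1], 1)
    expect_equal(pts$sensitivity[nrow(pts)], 1)
  })
})

test_that("bootstrap CI is deterministic given a seed and degenerate on separation", {
  sc <- c(5, 6, 7, 1, 2, 3); case <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ci1 <- bootstrap_auc_ci(sc, case, n_reps = 300, seed = 10)
  ci2 <- bootstrap_auc_ci(sc, case, n_reps = 300, seed = 10)
  expect_identical(ci1, ci2)
  expect_equal(unname(ci1), c(1, 1))
  expect_error(bootstrap_auc_ci(sc, case, n_reps = 50, seed = 1),
               "at least 200")
})

test_that("roc_result orders the interval around the point estimate", {
  withr::with_seed(8, {
    sc <- c(rnorm(100, 1.2), rnorm(150))
    case <- c(rep(TRUE, 100), rep(FALSE, 150))
    rr <- roc_result(sc, case, n_reps = 400, seed = 2)
    expect_lte(rr$ci_low, rr$auc)
    expect_gte(rr$ci_high, rr$auc)
    expect_gte(rr$ci_low, 0); expect_lte(rr$ci_high, 1)
    expect_equal(rr$n_cases, 100); expect_equal(rr$n_controls, 150)
  })
})

test_that("paired comparison is null for identical or shifted scores", {
  withr::with_seed(9, {
    sc <- rnorm(120); case <- c(rep(TRUE, 50), rep(FALSE, 70))
    r <- compare_auc_paired(sc, sc, case, n_reps = 300, seed = 1)
    expect_equal(r$delta, 0)
    expect_gt(r$p_value, 0.99)
    r2 <- compare_auc_paired(sc + 10, sc, case, n_reps = 300, seed = 1)
    expect_equal(r2$delta, 0)  # AUC is shift-invariant
  })
})

test_that("DeLong agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    case <- c(rep(TRUE, 80), rep(FALSE, 90))
    liab <- rnorm(170) + case
    a <- liab + rnorm(170, sd = 0.5)
    b <- liab + rnorm(170, sd = 0.9)
    ours <- compare_auc_paired(a, b, case, n_reps = 200, seed = 1)
    ref <- pROC::roc.test(pROC::roc(case, a, quiet = TRUE, direction = "<"),
                          pROC::roc(case, b, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(ours$auc_a, as.numeric(ref$roc1$auc), tolerance = 1e-12)
  })
})

test_that("the paired test detects a designed AUC gap", {
  # true AUCs 0.85 vs 0.75 on shared samples; expect frequent rejection
  rej <- withr::with_seed(17, {
    mu_a <- sqrt(2) * qnorm(0.85); mu_b <- sqrt(2) * qnorm(0.75)
    mean(vapply(1:40, function(i) {
      case <- c(rep(TRUE, 400), rep(FALSE, 400))
      a <- rnorm(800) + case * mu_a
      b <- rnorm(800) + case * mu_b
      compare_auc_paired(a, b, case, n_reps = 200, seed = i)$p_value < 0.05
    }, logical(1)))
  })
  expect_gt(rej, 0.8)
})

test_that("sensitivity/specificity curves respect extremes and monotonicity", {
  withr::with_seed(19, {
    sc <- rnorm(200); case <- rep(c(TRUE, FALSE), 100)
    pop <- rep("all", 200)
    lo <- min(sc) - 1; hi <- max(sc) + 1
    cur <- sens_spec_curve(sc, case, pop, c(lo, 0, hi))
    expect_equal(cur$sensitivity[1], 1); expect_equal(cur$specificity[1], 0)
    expect_equal(cur$sensitivity[3], 0); expect_equal(cur$specificity[3], 1)
    grid <- seq(lo, hi, length.out = 25)
    cur2 <- sens_spec_curve(sc, case, pop, grid)
    expect_true(all(diff(cur2$sensitivity) <= 0))
    expect_true(all(diff(cur2$specificity) >= 0))
    expect_error(sens_spec_curve(sc, case, pop, numeric(0)), "empty")
  })
})

test_that("populations shifted down lose sensitivity and gain specificity", {
  ch <- shifted_gaussian_cohort(seed = 23)
  grid <- seq(-3, 3, by = 0.25)
  cur <- sens_spec_curve(ch$scores, ch$samples$status,
                         ch$samples$population, grid)
  a <- cur[cur$population == "popA", ]
  b <- cur[cur$population == "popB", ]
  expect_true(all(b$sensitivity <= a$sensitivity + 1e-12))
  expect_true(all(b$specificity >= a$specificity - 1e-12))
})

test_that("confusion counts conserve class sizes", {
  r <- confusion_at_threshold(c(12, 10, 9, 13),
                              c(TRUE, TRUE, FALSE, FALSE), 11.5)
  expect_equal(c(r$TP, r$FN, r$TN, r$FP), c(1, 1, 1, 1))
  expect_equal(r$sensitivity, 0.5)
  r2 <- confusion_at_threshold(c(12, 10, 9, 13),
                               c(TRUE, TRUE, FALSE, FALSE), -Inf)
  expect_equal(c(r2$FN, r2$TN), c(0, 0))
  withr::with_seed(29, {
    sc <- rnorm(100); case <- rbinom(100, 1, 0.5) == 1
    r3 <- confusion_at_threshold(sc, case, 0.2)
    expect_equal(r3$TP + r3$FN, sum(case))
    expect_equal(r3$TN + r3$FP, sum(!case))
  })
})
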