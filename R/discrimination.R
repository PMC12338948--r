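#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `(#\{case > control\} + 0.5 #\{case = control\}) / (n_cases n_controls)`,
#' computed via midranks in O(n log n). Ties receive half credit.
#'
#' @param scores numeric vector, no missing values.
#' @param labels case/control labels; logical (`TRUE` = case), 0/1, or
#'   `"T1D"`/`"non_T1D"` tokens.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  case <- as_case_labels(labels)
  if (length(scores) != length(case)) stopf("scores and labels differ in length")
  if (anyNA(scores)) stopf("scores contain missing values")
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L) {
    stopf("AUC needs at least one case and one control (got %d/%d)", n1, n0)
  }
  r <- rank(scores)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Thresholds are the distinct score values in descending order (prepended
#' with `Inf`); at threshold `t`, predicted high risk is `score >= t`, so
#' `sensitivity = P(score >= t | case)` and
#' `specificity = P(score < t | control)`.
#'
#' @inheritParams auc
#' @return data.frame: `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  case <- as_case_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  cs <- sort(scores[case]); ct <- sort(scores[!case])
  n1 <- length(cs); n0 <- length(ct)
  # counts of scores >= t via findInterval on the sorted vectors
  sens <- (n1 - findInterval(thr, cs, left.open = TRUE)) / n1
  spec <- findInterval(thr, ct, left.open = TRUE) / n0
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' ROC summary with bootstrap confidence interval
#'
#' @inheritParams auc
#' @inheritParams bootstrap_auc_ci
#' @param ci compute the bootstrap interval?
#' @return List of class `roc_result`: `points` (see [roc_points()]), `auc`,
#'   `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @export
roc_result <- function(scores, labels, ci = TRUE, n_reps = 2000, seed = 1,
                       level = 0.95) {
  case <- as_case_labels(labels)
  interval <- if (ci) {
    bootstrap_auc_ci(scores, labels, n_reps = n_reps, seed = seed, level = level)
  } else {
    c(low = NA_real_, high = NA_real_)
  }
  structure(list(points = roc_points(scores, labels),
                 auc = auc(scores, labels),
                 ci_low = unname(interval[1]), ci_high = unname(interval[2]),
                 n_cases = sum(case), n_controls = sum(!case)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

# Fast AUC on pre-split score vectors (used in bootstrap loops).
auc_split <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Cases and controls are resampled separately with their sizes preserved;
#' the interval is the percentile interval of the resampled AUCs. All-tied
#' resamples are handled by the tie-aware estimator (AUC 0.5).
#'
#' @inheritParams auc
#' @param n_reps number of bootstrap resamples (at least 200).
#' @param seed integer seed; the same seed reproduces the interval exactly.
#' @param level coverage level in (0, 1), default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_reps = 2000, seed = 1,
                             level = 0.95) {
  if (n_reps < 200) stopf("n_reps must be at least 200")
  if (level <= 0 || level >= 1) stopf("level must lie in (0, 1)")
  case <- as_case_labels(labels)
  if (anyNA(scores)) stopf("scores contain missing values")
  x <- scores[case]; y <- scores[!case]
  if (!length(x) || !length(y)) stopf("need both classes for a bootstrap CI")
  n1 <- length(x); n0 <- length(y)
  stats_ <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      auc_split(x[sample.int(n1, n1, replace = TRUE)],
                y[sample.int(n0, n0, replace = TRUE)])
    }, numeric(1))
  })
  q <- stats::quantile(stats_, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(low = q[1], high = q[2])
}

# DeLong structural components: per-case and per-control placement values.
delong_placements <- function(scores, case) {
  x <- scores[case]; y <- scores[!case]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

# Paired DeLong test for two correlated AUCs on the same samples.
delong_test_paired <- function(scores_a, scores_b, case) {
  pa <- delong_placements(scores_a, case)
  pb <- delong_placements(scores_b, case)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$theta - pb$theta
  if (var_delta <= .Machine$double.eps) {
    p <- if (abs(delta) < 1e-12) 1 else 0
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(delta = delta, var = var_delta, z = z, p = p)
}

#' Paired comparison of two AUCs on the same samples
#'
#' Reports `delta = auc(a) - auc(b)`, a paired bootstrap percentile interval
#' (the same stratified resample indices applied to both score vectors), and
#' the p-value of DeLong's test for correlated ROC curves.
#'
#' @param scores_a,scores_b numeric scores for the identical samples.
#' @inheritParams bootstrap_auc_ci
#' @return List: `auc_a`, `auc_b`, `delta`, `ci` (`low`/`high`), `p_value`,
#'   `z`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels, n_reps = 2000,
                               seed = 1, level = 0.95) {
  if (length(scores_a) != length(scores_b)) {
    stopf("paired comparison requires scores on identical samples")
  }
  case <- as_case_labels(labels)
  if (length(case) != length(scores_a)) stopf("labels length mismatch")
  i1 <- which(case); i0 <- which(!case)
  n1 <- length(i1); n0 <- length(i0)
  if (!n1 || !n0) stopf("need both classes")
  deltas <- with_seed(seed, {
    vapply(seq_len(n_reps), function(k) {
      bi1 <- i1[sample.int(n1, n1, replace = TRUE)]
      bi0 <- i0[sample.int(n0, n0, replace = TRUE)]
      auc_split(scores_a[bi1], scores_a[bi0]) -
        auc_split(scores_b[bi1], scores_b[bi0])
    }, numeric(1))
  })
  q <- stats::quantile(deltas, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  dl <- delong_test_paired(scores_a, scores_b, case)
  list(auc_a = auc(scores_a, case), auc_b = auc(scores_b, case),
       delta = dl$delta, ci = c(low = q[1], high = q[2]),
       p_value = dl$p, z = dl$z)
}

#' Sensitivity/specificity against a shared threshold grid, per population
#'
#' For each population and threshold `t`: sensitivity is the proportion of
#' cases with `score >= t`, specificity the proportion of controls with
#' `score < t`. Populations with no cases yield `NA` sensitivity (and vice
#' versa), so control-only groups can still contribute specificity curves.
#'
#' @inheritParams auc
#' @param populations population label per sample.
#' @param thresholds numeric threshold grid (non-empty).
#' @return Long data.frame: `population`, `threshold`, `sensitivity`,
#'   `specificity`, `n_cases`, `n_controls`.
#' @export
sens_spec_curve <- function(scores, labels, populations, thresholds) {
  if (!length(thresholds)) stopf("threshold grid is empty")
  case <- as_case_labels(labels)
  pops <- unique(populations)
  out <- lapply(pops, function(p) {
    sel <- populations == p
    cs <- sort(scores[sel & case]); ct <- sort(scores[sel & !case])
    sens <- if (length(cs)) {
      (length(cs) - findInterval(thresholds, cs, left.open = TRUE)) / length(cs)
    } else NA_real_
    spec <- if (length(ct)) {
      findInterval(thresholds, ct, left.open = TRUE) / length(ct)
    } else NA_real_
    data.frame(population = p, threshold = thresholds,
               sensitivity = sens, specificity = spec,
               n_cases = length(cs), n_controls = length(ct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Confusion counts at a single risk threshold
#'
#' High risk is `score >= threshold` (the threshold itself classifies as
#' high risk).
#'
#' @inheritParams auc
#' @param threshold finite score cut-off.
#' @return One-row data.frame: `threshold`, `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `n_cases`, `n_controls`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  case <- as_case_labels(labels)
  high <- scores >= threshold
  tp <- sum(high & case); fn <- sum(!high & case)
  fp <- sum(high & !case); tn <- sum(!high & !case)
  data.frame(threshold = threshold, TP = tp, FP = fp, TN = tn, FN = fn,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
             n_cases = tp + fn, n_controls = tn + fp)
}

#' Per-population confusion report at one shared threshold
#'
#' @inheritParams sens_spec_curve
#' @param threshold finite score cut-off applied to every population.
#' @return data.frame with one row per population (see
#'   [confusion_at_threshold()]), plus a `population` column.
#' @export
threshold_report <- function(scores, labels, populations, threshold) {
  pops <- unique(populations)
  rows <- lapply(pops, function(p) {
    sel <- populations == p
    cbind(population = p,
          confusion_at_threshold(scores[sel], as_case_labels(labels)[sel],
                                 threshold))
  })
  do.call(rbind, rows)
}
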