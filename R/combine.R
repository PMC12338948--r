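#' Sum of two risk scores
#'
#' Optionally z-scores each input over the evaluated cohort before adding,
#' so scores on different scales contribute equally.
#'
#' @param a,b per-sample scores (numeric vectors or `score_result`s) on the
#'   same samples.
#' @param standardize `"zscore"` (default) or `"none"`.
#' @return Numeric vector of summed scores.
#' @export
summed_score <- function(a, b, standardize = c("zscore", "none")) {
  standardize <- match.arg(standardize)
  a <- as_score_vector(a); b <- as_score_vector(b)
  if (length(a) != length(b)) stopf("scores must cover the same samples")
  if (standardize == "zscore") {
    a <- zscore(a, "a"); b <- zscore(b, "b")
  }
  unname(a) + unname(b)
}

zscore <- function(x, label) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stopf("cannot z-score '%s': standard deviation is 0", label)
  }
  (x - mean(x)) / s
}

#' AUC-optimal weighted sum of two scores
#'
#' Z-scores both inputs, then scans mixing weights `w` in
#' `{0, grid_step, ..., 1}` for the combination `w a + (1 - w) b`
#' maximising the in-sample AUC. Ties are broken toward the weight nearest
#' 0.5 (then toward the smaller weight). The optimisation is in-sample;
#' pass `cv_folds` for an additional K-fold out-of-sample AUC estimate
#' (weights re-optimised on each training fold).
#'
#' @inheritParams summed_score
#' @param labels case/control labels (see [auc()]).
#' @param grid_step weight grid spacing in (0, 0.5], default 0.01.
#' @param cv_folds optional number of cross-validation folds.
#' @param seed seed for the fold split (only used with `cv_folds`).
#' @return List of class `combination_result`: `method = "opt_summed"`,
#'   `weight`, `auc`, `auc_components` (named `a`/`b`), `in_sample = TRUE`,
#'   `grid` (data.frame `w`, `auc`), and `cv_auc` when requested.
#' @export
optimal_weighted_sum <- function(a, b, labels, grid_step = 0.01,
                                 cv_folds = NULL, seed = 1) {
  if (grid_step <= 0 || grid_step > 0.5) stopf("grid_step must lie in (0, 0.5]")
  a <- as_score_vector(a); b <- as_score_vector(b)
  if (length(a) != length(b)) stopf("scores must cover the same samples")
  case <- as_case_labels(labels)
  za <- zscore(a, "a"); zb <- zscore(b, "b")
  ws <- seq(0, 1, by = grid_step)
  if (ws[length(ws)] < 1) ws <- c(ws, 1)
  aucs <- vapply(ws, function(w) auc(w * za + (1 - w) * zb, case), numeric(1))
  best <- which(aucs >= max(aucs) - 1e-12)
  pick <- best[order(abs(ws[best] - 0.5), ws[best])][1]
  out <- list(method = "opt_summed", weight = ws[pick], auc = aucs[pick],
              auc_components = c(a = auc(za, case), b = auc(zb, case)),
              in_sample = TRUE, grid = data.frame(w = ws, auc = aucs))
  if (!is.null(cv_folds)) {
    folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), length(a))))
    cv <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      wtr <- {
        atr <- vapply(ws, function(w) auc(w * za[tr] + (1 - w) * zb[tr],
                                          case[tr]), numeric(1))
        bidx <- which(atr >= max(atr) - 1e-12)
        ws[bidx[order(abs(ws[bidx] - 0.5), ws[bidx])][1]]
      }
      auc(wtr * za[!tr] + (1 - wtr) * zb[!tr], case[!tr])
    }, numeric(1))
    out$cv_auc <- mean(cv)
  }
  class(out) <- "combination_result"
  out
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("<combination_result> %s: weight %.3f, AUC %.4f (components a %.4f, b %.4f)%s\n",
              x$method, x$weight, x$auc, x$auc_components[["a"]],
              x$auc_components[["b"]],
              if (isTRUE(x$in_sample)) " [in-sample]" else ""))
  invisible(x)
}

# Weighted-dosage matrix (dosage * weight per linear variant).
weighted_dosages <- function(g, spec, variant_ids = NULL,
                             missing_policy = "mean_impute") {
  v <- spec$variants
  lin <- v[v$role == "linear", , drop = FALSE]
  if (!is.null(variant_ids)) {
    lin <- lin[match(variant_ids, lin$variant_id), , drop = FALSE]
    if (anyNA(lin$variant_id)) stopf("unknown linear variant id(s)")
  }
  j <- match(lin$variant_id, g$variant_ids)
  if (anyNA(j)) {
    stopf("variant(s) absent from genotype matrix: %s",
          paste(lin$variant_id[is.na(j)], collapse = ", "))
  }
  d <- resolve_missing(g$dosages[, j, drop = FALSE], missing_policy)
  sweep(d, 2L, lin$weight, "*")
}

#' Augment a base score with every subset of a small SNP panel
#'
#' For each of the `2^k - 1` non-empty subsets of the supplied weighted
#' dosage columns (e.g. the 7 SNPs of the African-ancestry score), reports
#' the AUC of `base_score + sum(subset columns)`; the unaugmented baseline
#' is reported as subset 0.
#'
#' @param base_scores per-sample base score (numeric or `score_result`).
#' @param snp_weighted_dosages samples x variants matrix of weighted
#'   dosages (see [weighted_dosages()]); at most 16 columns.
#' @param labels case/control labels.
#' @return data.frame: `bitmask` (bit i set = column i included),
#'   `variants` (comma-joined), `size`, `auc`; row 1 is the baseline.
#' @export
augment_with_snp_subsets <- function(base_scores, snp_weighted_dosages,
                                     labels) {
  base <- unname(as_score_vector(base_scores))
  m <- as.matrix(snp_weighted_dosages)
  if (nrow(m) != length(base)) stopf("dosage rows must match the base score")
  k <- ncol(m)
  if (k > 16) stopf("subset enumeration limited to 16 columns (got %d)", k)
  case <- as_case_labels(labels)
  ids <- colnames(m) %||% paste0("v", seq_len(k))
  masks <- 0:(2^k - 1)
  rows <- lapply(masks, function(mask) {
    inc <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    s <- base + if (length(inc)) rowSums(m[, inc, drop = FALSE]) else 0
    data.frame(bitmask = mask,
               variants = paste(ids[inc], collapse = ","),
               size = length(inc), auc = auc(s, case),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' AUC of every variant subset of a small score
#'
#' Enumerates all non-empty subsets of a definition's linear variants and
#' reports the AUC of each weighted sub-score; singletons give per-SNP
#' AUCs, complements of singletons the leave-one-out view, and the full set
#' reproduces the complete linear score.
#'
#' @param spec a [grs_definition()] whose linear variants number at most
#'   `max_variants`.
#' @param g aligned [genotype_matrix()].
#' @param labels case/control labels.
#' @param max_variants enumeration cap (default 12).
#' @param missing_policy see [linear_component()].
#' @return data.frame: `bitmask`, `variants`, `size`, `auc`, `is_singleton`,
#'   `is_loo` (complement of a singleton), `is_full`.
#' @export
subset_auc_enumeration <- function(spec, g, labels, max_variants = 12,
                                   missing_policy = "mean_impute") {
  lin_ids <- spec$variants$variant_id[spec$variants$role == "linear"]
  k <- length(lin_ids)
  if (k > max_variants) {
    stopf("definition has %d linear variants, above max_variants = %d; pass an explicit subset list instead",
          k, max_variants)
  }
  case <- as_case_labels(labels)
  masks <- seq_len(2^k - 1)
  rows <- lapply(masks, function(mask) {
    inc <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    # each sub-score goes through the same weighted-sum path as the full
    # score, so the full subset reproduces it exactly
    s <- linear_component(g, spec, lin_ids[inc], missing_policy)
    data.frame(bitmask = mask,
               variants = paste(lin_ids[inc], collapse = ","),
               size = length(inc), auc = auc(s, case),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$is_singleton <- out$size == 1L
  out$is_loo <- out$size == k - 1L
  out$is_full <- out$size == k
  out
}

#' Pearson correlations between risk scores
#'
#' Pairwise correlations of the per-sample totals over the combined case and
#' control samples.
#'
#' @param score_sets named list of per-sample scores (numeric vectors or
#'   `score_result`s) on identical samples; at least two.
#' @return Correlation matrix.
#' @export
grs_correlations <- function(score_sets) {
  if (!is.list(score_sets) || length(score_sets) < 2) {
    stopf("need a list of at least two score sets")
  }
  nm <- names(score_sets) %||% paste0("score", seq_along(score_sets))
  vs <- lapply(score_sets, function(s) unname(as_score_vector(s)))
  n <- unique(lengths(vs))
  if (length(n) != 1) stopf("score sets cover different sample counts")
  m <- do.call(cbind, vs)
  colnames(m) <- nm
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance score set(s): %s",
          paste(nm[sds == 0], collapse = ", "))
  }
  stats::cor(m)
}
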