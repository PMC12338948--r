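#' Per-SNP importance from weighted dosage differences
#'
#' For each linear variant s and population p, computes
#' `delta[p, s] = mean(w_s d_s | cases of p) - mean(w_s d_s | controls of p)`
#' -- the variant's contribution to the case-control gap in the mean score.
#' The population average weights populations equally. A variant is flagged
#' as important when its average delta exceeds `threshold` or any single
#' population's delta does (default 0.1, the rule used to shortlist the
#' most influential SNPs). When a definition carries DR-DQ tag SNPs, their
#' joint contribution can be appended as one combined interaction row by
#' passing the per-sample interaction component.
#'
#' @param g aligned [genotype_matrix()].
#' @param spec a [grs_definition()].
#' @param samples a [sample_table()] aligned to `g`'s samples.
#' @param threshold flagging threshold on the weighted-dosage difference
#'   (default 0.1).
#' @param interaction optional per-sample interaction component (named
#'   numeric vector or the `interaction` column of a `score_result`);
#'   reported as a single `DR-DQ_interaction` row.
#' @param missing_policy see [linear_component()].
#' @return data.frame: `variant_id`, one `delta_<population>` column per
#'   population, `average_delta`, `flagged`, sorted by decreasing
#'   `average_delta`.
#' @export
snp_importance <- function(g, spec, samples, threshold = 0.1,
                           interaction = NULL,
                           missing_policy = "mean_impute") {
  samples <- match_samples(samples, g$sample_ids)
  case <- samples$status == "T1D"
  pops <- unique(samples$population)
  wd <- weighted_dosages(g, spec, missing_policy = missing_policy)
  rows_ids <- colnames(wd) <- spec$variants$variant_id[spec$variants$role == "linear"]
  if (!is.null(interaction)) {
    wd <- cbind(wd, `DR-DQ_interaction` = unname(interaction))
    rows_ids <- colnames(wd)
  }
  deltas <- matrix(NA_real_, ncol(wd), length(pops),
                   dimnames = list(rows_ids, pops))
  used <- logical(length(pops))
  for (p in seq_along(pops)) {
    sel <- samples$population == pops[p]
    if (!any(sel & case) || !any(sel & !case)) {
      warnf("population '%s' lacks a class; omitted from the average", pops[p])
      next
    }
    used[p] <- TRUE
    deltas[, p] <- colMeans(wd[sel & case, , drop = FALSE]) -
      colMeans(wd[sel & !case, , drop = FALSE])
  }
  avg <- rowMeans(deltas[, used, drop = FALSE])
  flagged <- avg > threshold |
    apply(deltas[, used, drop = FALSE] > threshold, 1L, any)
  out <- data.frame(variant_id = rows_ids, deltas,
                    average_delta = avg, flagged = unname(flagged),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1 + seq_along(pops)] <- paste0("delta_", pops)
  out <- out[order(-out$average_delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-ranked important SNPs
#'
#' Convenience wrapper around [snp_importance()] returning the `n` variants
#' with the largest population-averaged weighted-dosage difference.
#'
#' @inheritParams snp_importance
#' @param n number of variants to keep (default 11).
#' @return The top `n` rows of [snp_importance()].
#' @export
top_important_snps <- function(g, spec, samples, n = 11, threshold = 0.1,
                               missing_policy = "mean_impute") {
  imp <- snp_importance(g, spec, samples, threshold = threshold,
                        missing_policy = missing_policy)
  utils::head(imp, n)
}

#' Effect-allele frequencies per variant, population and status
#'
#' Frequency is half the mean dosage within each group. Each row is
#' annotated with the allele's direction of effect (risk-increasing for
#' positive weight, protective for negative) and the absolute weight, ready
#' for allele-frequency scatter plots with effect-scaled markers.
#'
#' @inheritParams snp_importance
#' @return data.frame: `variant_id`, `population`, `status`, `n`,
#'   `frequency`, `direction`, `abs_weight`.
#' @export
allele_frequency_table <- function(g, spec, samples) {
  samples <- match_samples(samples, g$sample_ids)
  v <- spec$variants
  j <- match(v$variant_id, g$variant_ids)
  if (anyNA(j)) {
    stopf("variant(s) absent from genotype matrix: %s",
          paste(v$variant_id[is.na(j)], collapse = ", "))
  }
  d <- g$dosages[, j, drop = FALSE]
  groups <- split(seq_len(nrow(d)),
                  list(population = samples$population,
                       status = samples$status), drop = TRUE)
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    parts <- strsplit(gname, ".", fixed = TRUE)[[1]]
    data.frame(variant_id = v$variant_id,
               population = parts[1], status = parts[2], n = length(idx),
               frequency = colMeans(d[idx, , drop = FALSE], na.rm = TRUE) / 2,
               direction = ifelse(v$weight >= 0, "risk", "protective"),
               abs_weight = abs(v$weight),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dosage correlations between two variant sets
#'
#' Pearson correlations between the dosage columns of `set_a` and `set_b`
#' (pairwise-complete observations). Zero-variance columns yield `NA`
#' entries rather than an error.
#'
#' @param g [genotype_matrix()].
#' @param set_a,set_b character vectors of variant ids present in `g`.
#' @return `length(set_a)` x `length(set_b)` correlation matrix.
#' @export
snp_cross_correlations <- function(g, set_a, set_b) {
  ja <- match(set_a, g$variant_ids); jb <- match(set_b, g$variant_ids)
  if (anyNA(ja) || anyNA(jb)) {
    stopf("variant(s) absent from genotype matrix: %s",
          paste(c(set_a[is.na(ja)], set_b[is.na(jb)]), collapse = ", "))
  }
  da <- g$dosages[, ja, drop = FALSE]
  db <- g$dosages[, jb, drop = FALSE]
  suppressWarnings(stats::cor(da, db, use = "pairwise.complete.obs"))
}
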