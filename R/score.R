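#' Weighted linear score component
#'
#' Computes, per sample, the weighted sum of effect-allele dosages over the
#' `role = "linear"` variants of a definition (or an explicit subset of
#' them). Missing dosages are handled per `missing_policy`: `mean_impute`
#' substitutes the within-input mean dosage of the variant, `zero`
#' substitutes 0, `fail` raises an error naming the affected samples and
#' variants.
#'
#' @param g aligned [genotype_matrix()].
#' @param spec a [grs_definition()].
#' @param variant_ids optional subset of linear variant ids to sum over.
#' @param missing_policy one of `"mean_impute"`, `"zero"`, `"fail"`.
#' @return Named numeric vector of per-sample sums.
#' @export
linear_component <- function(g, spec, variant_ids = NULL,
                             missing_policy = c("mean_impute", "zero", "fail")) {
  missing_policy <- match.arg(missing_policy)
  v <- spec$variants
  lin <- v[v$role == "linear", , drop = FALSE]
  if (!is.null(variant_ids)) {
    bad <- setdiff(variant_ids, lin$variant_id)
    if (length(bad)) {
      stopf("not linear variants of this definition: %s",
            paste(bad, collapse = ", "))
    }
    lin <- lin[match(variant_ids, lin$variant_id), , drop = FALSE]
  }
  if (!nrow(lin)) {
    return(stats::setNames(numeric(length(g$sample_ids)), g$sample_ids))
  }
  j <- match(lin$variant_id, g$variant_ids)
  if (anyNA(j)) {
    stopf("variant(s) absent from the genotype matrix: %s",
          paste(lin$variant_id[is.na(j)], collapse = ", "))
  }
  d <- g$dosages[, j, drop = FALSE]
  d <- resolve_missing(d, missing_policy)
  drop(d %*% lin$weight) |> stats::setNames(g$sample_ids)
}

resolve_missing <- function(d, missing_policy) {
  if (!anyNA(d)) return(d)
  if (missing_policy == "fail") {
    idx <- which(is.na(d), arr.ind = TRUE)
    stopf("missing dosages under missing_policy='fail': %s",
          paste(utils::head(sprintf("%s/%s", rownames(d)[idx[, 1]],
                                    colnames(d)[idx[, 2]]), 5),
                collapse = ", "))
  }
  if (missing_policy == "zero") {
    d[is.na(d)] <- 0
    return(d)
  }
  # mean_impute: within-input per-variant mean; all-missing columns fall
  # back to 0 (no information at all about the variant in this cohort).
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na_idx <- which(is.na(d), arr.ind = TRUE)
  d[na_idx] <- mu[na_idx[, 2]]
  d
}

# Per-variant missingness report for a scoring run.
missingness_report <- function(g, spec) {
  j <- match(spec$variants$variant_id, g$variant_ids)
  frac <- ifelse(is.na(j), 1,
                 colMeans(is.na(g$dosages))[j])
  data.frame(variant_id = spec$variants$variant_id,
             missing_fraction = as.numeric(frac),
             stringsAsFactors = FALSE)
}

#' Call DR-DQ diplotypes from tag-SNP dosages
#'
#' Each tag dosage is rounded to the nearest integer in {0, 1, 2}; dosages
#' farther than `hard_call_threshold` from every integer are still rounded
#' but flagged as ambiguous. Haplotype copies are then assigned greedily by
#' descending rounded dosage (ties broken by the pre-rounding dosage, then
#' tag order) until two copies are placed; unfilled slots become `OTHER`.
#' A tag with rounded dosage 2 fills both slots. If rounded dosages sum to
#' more than 2, the two largest pre-rounding dosages win and the conflict is
#' flagged; valid input never raises.
#'
#' @param tag_dosages samples x haplotypes numeric matrix; column names are
#'   haplotype names (use [tag_dosage_matrix()] to build one from a
#'   genotype matrix and definition). Missing dosages are treated as 0.
#' @param hard_call_threshold rounding tolerance in (0, 0.5], default 0.5.
#' @return data.frame of class `diplotype_calls`: `sample_id`, `hap1`,
#'   `hap2` (unordered; `OTHER` = untagged haplotype), `tag_dosage_sum`,
#'   `ambiguous`, `conflict`.
#' @export
call_drdq_diplotype <- function(tag_dosages, hard_call_threshold = 0.5) {
  if (!is.matrix(tag_dosages)) tag_dosages <- as.matrix(tag_dosages)
  if (is.null(colnames(tag_dosages))) {
    stopf("tag_dosages must have haplotype names as column names")
  }
  if (hard_call_threshold <= 0 || hard_call_threshold > 0.5) {
    stopf("hard_call_threshold must lie in (0, 0.5]")
  }
  haps <- colnames(tag_dosages)
  n <- nrow(tag_dosages)
  d <- tag_dosages
  d[is.na(d)] <- 0
  r <- pmin(pmax(round(d), 0), 2)
  ambiguous <- rowSums(abs(d - r) > hard_call_threshold + 1e-12) > 0
  rs <- rowSums(r)
  conflict <- rs > 2

  hap1 <- rep("OTHER", n)
  hap2 <- rep("OTHER", n)
  if (any(conflict)) {
    # keep the two largest pre-rounding dosages, truncated to two copies
    for (i in which(conflict)) {
      ord <- order(-d[i, ], seq_along(haps))
      top1 <- ord[1]; top2 <- ord[2]
      ri <- numeric(length(haps))
      ri[top1] <- min(r[i, top1], 2)
      if (ri[top1] < 2) ri[top2] <- min(r[i, top2], 2 - ri[top1])
      r[i, ] <- ri
    }
  }
  if (n) {
    # greedy assignment, vectorised: rank by rounded dosage, then raw
    # dosage, then tag order (r dominates the key since d < 2.5 < 10)
    key <- r * 10 + d
    j1 <- max.col(key, ties.method = "first")
    r1 <- r[cbind(seq_len(n), j1)]
    hap1[r1 >= 1] <- haps[j1[r1 >= 1]]
    hap2[r1 >= 2] <- haps[j1[r1 >= 2]]
    second <- which(r1 == 1)
    if (length(second)) {
      key[cbind(second, j1[second])] <- -1
      k2 <- key[second, , drop = FALSE]
      j2 <- max.col(k2, ties.method = "first")
      r2 <- r[cbind(second, j2)]
      hit <- r2 >= 1
      hap2[second[hit]] <- haps[j2[hit]]
    }
  }
  structure(
    data.frame(sample_id = rownames(tag_dosages) %||% as.character(seq_len(n)),
               hap1 = hap1, hap2 = hap2,
               tag_dosage_sum = rowSums(tag_dosages, na.rm = TRUE),
               ambiguous = ambiguous, conflict = conflict,
               stringsAsFactors = FALSE),
    class = c("diplotype_calls", "data.frame"))
}

#' Tag-dosage matrix for a definition's DR-DQ haplotypes
#'
#' @param g aligned [genotype_matrix()].
#' @param spec a [grs_definition()] with `haplotype_tag` variants.
#' @return samples x haplotypes dosage matrix (columns named by haplotype).
#' @export
tag_dosage_matrix <- function(g, spec) {
  tags <- haplotype_tags(spec)
  if (!length(tags)) stopf("definition %s has no haplotype tags", spec$name)
  j <- match(tags, g$variant_ids)
  if (anyNA(j)) {
    stopf("tag variant(s) absent from genotype matrix: %s",
          paste(tags[is.na(j)], collapse = ", "))
  }
  m <- g$dosages[, j, drop = FALSE]
  colnames(m) <- names(tags)
  m
}

#' Diplotype interaction component
#'
#' Looks up the interaction weight of each sample's unordered haplotype
#' pair; pairs absent from the table, and any pair involving `OTHER`,
#' contribute 0.
#'
#' @param calls a `diplotype_calls` data.frame from [call_drdq_diplotype()].
#' @param spec a [grs_definition()] carrying the interaction table.
#' @return Named numeric vector of per-sample interaction weights.
#' @export
interaction_component <- function(calls, spec) {
  lut <- interaction_lookup(spec)
  w <- unname(lut[pair_key(calls$hap1, calls$hap2)])
  w[is.na(w)] <- 0
  stats::setNames(w, calls$sample_id)
}

# GRS1-style combination contribution: 9-cell lookup on the hard-called
# genotypes of the two combination variants.
combination_component <- function(g, spec, missing_policy) {
  cb <- spec$combinations
  if (is.null(cb)) {
    return(stats::setNames(numeric(length(g$sample_ids)), g$sample_ids))
  }
  ids <- spec$variants$variant_id[spec$variants$role == "combination"]
  j <- match(ids, g$variant_ids)
  if (anyNA(j)) {
    stopf("combination variant(s) absent from genotype matrix: %s",
          paste(ids[is.na(j)], collapse = ", "))
  }
  d <- resolve_missing(g$dosages[, j, drop = FALSE], missing_policy)
  ga <- pmin(pmax(round(d[, 1]), 0), 2)
  gb <- pmin(pmax(round(d[, 2]), 0), 2)
  lut <- stats::setNames(cb$weight, paste(cb$geno_a, cb$geno_b))
  stats::setNames(unname(lut[paste(ga, gb)]), g$sample_ids)
}

#' Compute a genetic risk score
#'
#' Dispatches on the definition's structure: the 67-SNP-style score is the
#' DR-DQ diplotype interaction term plus the weighted linear sum over the
#' remaining HLA and non-HLA SNPs; the 30-SNP-style score is its 28-SNP
#' linear sum plus the 2-SNP DR3/DR4-DQ8 combination lookup; a pure linear
#' definition (e.g. the 7-SNP African-ancestry score) is just the weighted
#' sum.
#'
#' @param g [genotype_matrix()] aligned to `spec` (see [align_genotypes()]).
#' @param spec a [grs_definition()].
#' @param missing_policy missing-dosage policy, see [linear_component()].
#' @param hard_call_threshold passed to [call_drdq_diplotype()].
#' @return A data.frame of class `score_result` with columns `sample_id`,
#'   `total`, `interaction`, `hla_linear`, `non_hla_linear` where
#'   `total = interaction + hla_linear + non_hla_linear`. The `interaction`
#'   column houses the diplotype interaction (67-SNP style) or the
#'   combination contribution (30-SNP style); it is 0 for pure linear
#'   scores. Attributes: `grs_name`, `diplotype_calls` (when tags exist),
#'   `missingness` report.
#' @export
score <- function(g, spec, missing_policy = c("mean_impute", "zero", "fail"),
                  hard_call_threshold = 0.5) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "grs_definition"))
  v <- spec$variants
  lin <- v[v$role == "linear", , drop = FALSE]
  hla_ids <- lin$variant_id[lin$region != "non_hla"]
  non_hla_ids <- lin$variant_id[lin$region == "non_hla"]
  hla_linear <- linear_component(g, spec, hla_ids, missing_policy)
  non_hla_linear <- linear_component(g, spec, non_hla_ids, missing_policy)
  # the total uses one weighted sum over all linear variants, so it is
  # bitwise-consistent with subset enumeration; the component split is
  # additive to floating tolerance
  all_linear <- linear_component(g, spec, lin$variant_id, missing_policy)

  calls <- NULL
  if (any(v$role == "haplotype_tag")) {
    calls <- call_drdq_diplotype(tag_dosage_matrix(g, spec),
                                 hard_call_threshold)
    inter <- interaction_component(calls, spec)
  } else if (any(v$role == "combination")) {
    inter <- combination_component(g, spec, missing_policy)
  } else {
    inter <- stats::setNames(numeric(length(g$sample_ids)), g$sample_ids)
  }

  res <- data.frame(sample_id = g$sample_ids,
                    total = unname(inter + all_linear),
                    interaction = unname(inter),
                    hla_linear = unname(hla_linear),
                    non_hla_linear = unname(non_hla_linear),
                    stringsAsFactors = FALSE)
  class(res) <- c("score_result", "data.frame")
  attr(res, "grs_name") <- spec$name
  attr(res, "has_tags") <- any(v$role == "haplotype_tag")
  if (!is.null(calls)) attr(res, "diplotype_calls") <- calls
  attr(res, "missingness") <- missingness_report(g, spec)
  res
}

#' Split a 67-SNP-style score into HLA and non-HLA parts
#'
#' The HLA part is the diplotype interaction term plus the linear sum over
#' the other HLA SNPs (14 tags + 21 linear = 35 SNPs in the packaged
#' definition); the non-HLA part is the 32-SNP linear remainder. The two
#' parts sum to the total score. Defined only for definitions with DR-DQ
#' tags; pure linear and combination-rule scores have no published split.
#'
#' @param r a `score_result` from [score()] on a tagged definition.
#' @return data.frame: `sample_id`, `hla_score`, `non_hla_score`.
#' @export
split_hla_nonhla <- function(r) {
  stopifnot(inherits(r, "score_result"))
  if (!isTRUE(attr(r, "has_tags"))) {
    stopf("HLA/non-HLA split is defined only for DR-DQ-tagged scores, not %s",
          attr(r, "grs_name") %||% "this score")
  }
  data.frame(sample_id = r$sample_id,
             hla_score = r$interaction + r$hla_linear,
             non_hla_score = r$non_hla_linear,
             stringsAsFactors = FALSE)
}

#' Write per-sample scores
#' @param r a `score_result`.
#' @param path output path (tab-separated).
#' @export
write_score_table <- function(r, path) {
  utils::write.table(as.data.frame(r), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
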