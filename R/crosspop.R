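#' Cross-population AUC mismatch matrix
#'
#' For every ordered pair of populations (i, j), computes the AUC of
#' population i's cases against population j's controls, subtracts the
#' "expected" AUC, and reports the difference. Under the default
#' `case_population` convention the expected value for cell (i, j) is the
#' within-population AUC of case population i; under `mean_within` it is the
#' mean of the two populations' within-population AUCs. Matched cells (i, i)
#' are exactly 0 under both conventions. Positive cells mean the mismatched
#' comparison overstates discrimination; negative cells understate it.
#'
#' @param scores per-sample numeric scores (or a `score_result`).
#' @param samples a [sample_table()] aligned to `scores` (matched by
#'   `sample_id` when scores are named or a `score_result`, else by
#'   position).
#' @param convention `"case_population"` or `"mean_within"`.
#' @return List of class `auc_delta_matrix`: `raw_auc`, `expected`, `delta`
#'   (case populations x control populations), `within` (named vector) and
#'   `convention`.
#' @export
crosspop_delta_matrix <- function(scores, samples,
                                  convention = c("case_population",
                                                 "mean_within")) {
  convention <- match.arg(convention)
  al <- align_scores_samples(scores, samples)
  sc <- al$scores; samples <- al$samples
  case <- samples$status == "T1D"
  pops <- unique(samples$population)
  for (p in pops) {
    if (!any(case & samples$population == p)) {
      stopf("population '%s' has no cases", p)
    }
    if (!any(!case & samples$population == p)) {
      stopf("population '%s' has no controls", p)
    }
  }
  k <- length(pops)
  raw <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) {
    cs <- sc[case & samples$population == pops[i]]
    for (j in seq_len(k)) {
      ct <- sc[!case & samples$population == pops[j]]
      raw[i, j] <- auc_split(cs, ct)
    }
  }
  within <- diag(raw)
  expected <- switch(convention,
    case_population = matrix(within, k, k, byrow = FALSE,
                             dimnames = dimnames(raw)),
    mean_within = (matrix(within, k, k) + matrix(within, k, k, byrow = TRUE)) / 2
  )
  dimnames(expected) <- dimnames(raw)
  structure(list(raw_auc = raw, expected = expected, delta = raw - expected,
                 within = stats::setNames(within, pops),
                 convention = convention),
            class = "auc_delta_matrix")
}

#' @export
print.auc_delta_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<auc_delta_matrix> (%s convention) delta = raw - expected:\n",
              x$convention))
  print(round(x$delta, digits))
  invisible(x)
}

#' Long-format view of an AUC delta matrix
#' @param x an `auc_delta_matrix`.
#' @param ... unused.
#' @return data.frame: `case_population`, `control_population`, `raw_auc`,
#'   `expected`, `delta` (heatmap-ready).
#' @export
as.data.frame.auc_delta_matrix <- function(x, ...) {
  k <- nrow(x$raw_auc)
  data.frame(
    case_population = rep(rownames(x$raw_auc), times = k),
    control_population = rep(colnames(x$raw_auc), each = k),
    raw_auc = as.vector(x$raw_auc),
    expected = as.vector(x$expected),
    delta = as.vector(x$delta),
    stringsAsFactors = FALSE)
}

#' AUC of one population's cases against pooled, undersampled controls
#'
#' Emulates assessing a score when the control set mixes populations: for
#' the given case population, controls are pooled from each evaluated
#' mixture after undersampling every included control population (without
#' replacement, seeded) down to the size of the smallest one, so each
#' population carries equal weight. The mixtures evaluated are the case
#' population's own controls alone, its controls plus each other population
#' pairwise, and its controls plus all others. Each supplied score set
#' (e.g. two competing GRSs) is evaluated against the identical pooled
#' control draw.
#'
#' @param scores named list of per-sample score vectors (or `score_result`s),
#'   one per GRS; a bare vector is treated as a single unnamed score.
#' @param samples a [sample_table()].
#' @param case_pop population supplying the cases.
#' @param control_pops populations considered as control sources; defaults
#'   to every population in `samples`.
#' @param equalize undersample to the smallest included control set
#'   (default `TRUE`); with `FALSE` all controls are pooled as-is.
#' @param n_per_pop optional explicit per-population control count; errors
#'   if any included population has fewer controls (no upsampling).
#' @param seed integer seed for the control draw.
#' @param redraws number of independent undersampling draws to average over
#'   (default 1, a single draw).
#' @return data.frame: `mixture` (comma-joined control populations), `grs`,
#'   `auc`, `n_control_pops`, `n_controls`.
#' @export
mixed_control_auc <- function(scores, samples, case_pop, control_pops = NULL,
                              equalize = TRUE, n_per_pop = NULL, seed = 1,
                              redraws = 1) {
  if (!is.list(scores)) scores <- list(score = scores)
  if (is.null(names(scores))) names(scores) <- paste0("score", seq_along(scores))
  al <- lapply(scores, function(s) align_scores_samples(s, samples))
  samples <- al[[1]]$samples
  score_mat <- vapply(al, function(a) a$scores, numeric(nrow(samples)))
  case <- samples$status == "T1D"
  pops <- unique(samples$population)
  if (!case_pop %in% pops) stopf("unknown case population '%s'", case_pop)
  control_pops <- control_pops %||% pops
  others <- setdiff(control_pops, case_pop)
  if (equalize && length(control_pops) < 2) {
    stopf("equalize=TRUE requires at least two control populations")
  }
  mixtures <- c(list(case_pop),
                lapply(others, function(p) c(case_pop, p)),
                if (length(others) > 1) list(c(case_pop, others)))

  ctrl_idx <- lapply(pops, function(p) which(!case & samples$population == p))
  names(ctrl_idx) <- pops
  n_ctrl <- vapply(ctrl_idx, length, integer(1))
  case_idx <- which(case & samples$population == case_pop)
  if (!length(case_idx)) stopf("population '%s' has no cases", case_pop)

  seeds <- derive_seeds(seed, redraws)
  rows <- list()
  for (m in mixtures) {
    take <- if (!is.null(n_per_pop)) {
      n_per_pop
    } else if (equalize) {
      min(n_ctrl[m])
    } else {
      NA_integer_
    }
    if (!is.na(take) && any(n_ctrl[m] < take)) {
      short <- m[n_ctrl[m] < take][1]
      stopf("population '%s' has only %d controls, fewer than the requested %d (no upsampling)",
            short, n_ctrl[short], take)
    }
    aucs <- matrix(NA_real_, redraws, ncol(score_mat))
    for (r in seq_len(redraws)) {
      pooled <- with_seed(seeds[r], {
        unlist(lapply(m, function(p) {
          idx <- ctrl_idx[[p]]
          if (is.na(take) || take == length(idx)) idx
          else idx[sample.int(length(idx), take)]
        }))
      })
      for (g in seq_len(ncol(score_mat))) {
        aucs[r, g] <- auc_split(score_mat[case_idx, g], score_mat[pooled, g])
      }
    }
    n_pool <- if (is.na(take)) sum(n_ctrl[m]) else take * length(m)
    rows[[length(rows) + 1L]] <- data.frame(
      mixture = paste(m, collapse = ","), grs = colnames(score_mat),
      auc = colMeans(aucs), n_control_pops = length(m), n_controls = n_pool,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score distribution summaries per population and status
#'
#' @param scores per-sample numeric scores (or a `score_result`).
#' @param samples a [sample_table()].
#' @param breaks optional numeric bin breaks; when given, histogram counts
#'   on that shared grid are attached as attribute `histogram` (long
#'   data.frame with `bin_low`, `bin_high`, `count`). Scores outside the
#'   grid fall into the outermost bins.
#' @return data.frame with one row per (population, status): `n`, `mean`,
#'   `sd`, quartiles `q25`/`q50`/`q75`, and deciles `d10`..`d90`.
#' @export
distribution_summary <- function(scores, samples, breaks = NULL) {
  al <- align_scores_samples(scores, samples)
  sc <- al$scores; samples <- al$samples
  groups <- split(sc, list(population = samples$population,
                           status = samples$status), drop = TRUE)
  qs <- c(0.25, 0.5, 0.75)
  ds <- seq(0.1, 0.9, by = 0.1)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    qv <- stats::quantile(x, qs, names = FALSE)
    dv <- stats::quantile(x, ds, names = FALSE)
    cbind(data.frame(population = parts[1], status = parts[2],
                     n = length(x), mean = mean(x),
                     sd = if (length(x) > 1) stats::sd(x) else 0,
                     q25 = qv[1], q50 = qv[2], q75 = qv[3],
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(as.list(dv)),
                          paste0("d", ds * 100)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(breaks)) {
    if (length(breaks) < 2 || is.unsorted(breaks, strictly = TRUE)) {
      stopf("breaks must be a strictly increasing vector of length >= 2")
    }
    hist_rows <- lapply(names(groups), function(g) {
      x <- pmin(pmax(groups[[g]], breaks[1]), breaks[length(breaks)])
      parts <- strsplit(g, ".", fixed = TRUE)[[1]]
      h <- graphics::hist(x, breaks = breaks, plot = FALSE)
      data.frame(population = parts[1], status = parts[2],
                 bin_low = utils::head(breaks, -1), bin_high = breaks[-1],
                 count = h$counts, stringsAsFactors = FALSE)
    })
    attr(out, "histogram") <- do.call(rbind, hist_rows)
  }
  out
}

# Align a score vector (possibly named / a score_result) with a sample
# table; returns list(scores, samples) in a consistent row order.
align_scores_samples <- function(scores, samples) {
  sc <- as_score_vector(scores)
  if (!inherits(samples, "sample_table")) {
    samples <- sample_table(samples$sample_id, samples$population,
                            samples$status)
  }
  if (!is.null(names(sc))) {
    samples <- match_samples(samples, names(sc))
  } else if (length(sc) != nrow(samples)) {
    stopf("unnamed scores must match the sample table length (%d vs %d)",
          length(sc), nrow(samples))
  }
  list(scores = unname(sc), samples = samples)
}
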