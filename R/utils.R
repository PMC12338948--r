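# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of sub-seeds from one master seed, kept inside the 32-bit
# integer range expected by set.seed().
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 10007L * seq_len(n)) %% .Machine$integer.max
}

#' Normalise case/control labels to a logical vector (TRUE = case)
#'
#' Accepts logical vectors, 0/1 numerics, factors, or character vectors using
#' the `T1D`/`non_T1D` tokens (also `case`/`control`).
#' @noRd
as_case_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0 (control) or 1 (case)", call. = FALSE)
    }
    return(labels == 1)
  }
  if (is.character(labels)) {
    case_tok <- c("T1D", "case", "1")
    ctrl_tok <- c("non_T1D", "control", "0")
    bad <- setdiff(unique(labels), c(case_tok, ctrl_tok))
    if (length(bad)) {
      stop("unrecognised status labels: ", paste(bad, collapse = ", "),
           " (expected T1D/non_T1D)", call. = FALSE)
    }
    return(labels %in% case_tok)
  }
  stop("cannot interpret labels of class ", class(labels)[1], call. = FALSE)
}

# Extract a per-sample numeric score from either a numeric vector or a
# score_result.
as_score_vector <- function(x) {
  if (inherits(x, "score_result")) return(stats::setNames(x$total, x$sample_id))
  if (is.numeric(x)) return(x)
  stop("expected a numeric vector or a score_result", call. = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
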