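#' Genotype dosage matrices
#'
#' A `genotype_matrix` holds effect-allele dosages (samples x variants, each
#' entry in \[0, 2\] or `NA` for missing) plus a per-variant hard-call flag
#' (all observed dosages in {0, 1, 2}).
#'
#' @param dosages numeric matrix, samples in rows and variants in columns;
#'   `rownames`/`colnames` are used when `sample_ids`/`variant_ids` are not
#'   given.
#' @param sample_ids,variant_ids unique identifier vectors.
#' @return An object of class `genotype_matrix` with elements `dosages`
#'   (named matrix), `sample_ids`, `variant_ids` and `is_hard_call`.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, variant_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  sample_ids <- as.character(sample_ids %||% rownames(dosages))
  variant_ids <- as.character(variant_ids %||% colnames(dosages))
  if (length(sample_ids) != nrow(dosages) || any(!nzchar(sample_ids))) {
    stopf("sample_ids must name every row")
  }
  if (length(variant_ids) != ncol(dosages) || any(!nzchar(variant_ids))) {
    stopf("variant_ids must name every column")
  }
  if (anyDuplicated(sample_ids)) stopf("duplicate sample ids")
  if (anyDuplicated(variant_ids)) stopf("duplicate variant ids")
  rng <- range(dosages, na.rm = TRUE)
  if (nrow(dosages) && any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    stopf("dosages must lie in [0, 2]; found range [%g, %g]", rng[1], rng[2])
  }
  dimnames(dosages) <- list(sample_ids, variant_ids)
  structure(
    list(
      dosages = dosages,
      sample_ids = sample_ids,
      variant_ids = variant_ids,
      is_hard_call = apply(dosages, 2L, function(d) {
        all(is.na(d)) || all(d[!is.na(d)] %in% c(0, 1, 2))
      })
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d hard-call, %.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$is_hard_call),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

DOSAGE_NA_TOKENS <- c("NA", ".", "")

#' Read a dosage table
#'
#' Tab-separated, first column `sample_id`, remaining columns one variant
#' each with numeric dosages in \[0, 2\]; `NA`, `.` or an empty field denote
#' a missing dosage.
#'
#' @param path file path.
#' @return A [genotype_matrix()].
#' @export
read_dosage_table <- function(path) {
  if (!file.exists(path)) stopf("dosage table not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = DOSAGE_NA_TOKENS,
                         colClasses = "character")
  if (!ncol(d) || names(d)[1] != "sample_id") {
    stopf("first column of a dosage table must be 'sample_id'")
  }
  ids <- d[[1]]
  m <- matrix(NA_real_, nrow(d), ncol(d) - 1L,
              dimnames = list(ids, names(d)[-1]))
  for (j in seq_len(ncol(d) - 1L)) {
    raw <- d[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stopf("non-numeric dosage '%s' at row %d, column '%s'",
            raw[bad[1]], bad[1], names(d)[j + 1L])
    }
    out <- which(!is.na(num) & (num < 0 | num > 2))
    if (length(out)) {
      stopf("dosage %g out of [0, 2] at row %d, column '%s'",
            num[out[1]], out[1], names(d)[j + 1L])
    }
    m[, j] <- num
  }
  genotype_matrix(m)
}

#' Write a dosage table
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_dosage_table <- function(g, path) {
  d <- data.frame(sample_id = g$sample_ids, g$dosages,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Align genotypes to a GRS definition's effect alleles
#'
#' Reorients source dosages so that every column counts copies of the
#' definition's effect allele: variants whose source (ref, alt) pair is
#' swapped relative to the definition are flipped (`d -> 2 - d`); variants
#' with a non-matching allele pair, strand-ambiguous variants (A/T or C/G)
#' matching neither orientation, and variants absent from the source are set
#' entirely missing and listed in the alignment report. Output columns
#' follow the definition's variant order.
#'
#' @param raw [genotype_matrix()] as read from the source, with alt-allele
#'   dosages.
#' @param spec a [grs_definition()].
#' @param allele_map data.frame with columns `variant_id`, `ref`, `alt`
#'   describing the source orientation of each available variant.
#' @return An aligned [genotype_matrix()] with attribute
#'   `alignment_report` (data.frame: `variant_id`, `action` one of
#'   `ok`, `flipped`, `mismatch`, `ambiguous`, `absent`).
#' @export
align_genotypes <- function(raw, spec, allele_map) {
  stopifnot(inherits(raw, "genotype_matrix"), inherits(spec, "grs_definition"))
  allele_map <- as.data.frame(allele_map, stringsAsFactors = FALSE)
  need <- setdiff(c("variant_id", "ref", "alt"), names(allele_map))
  if (length(need)) stopf("allele_map missing column(s): %s", paste(need, collapse = ", "))

  v <- spec$variants
  n <- nrow(raw$dosages)
  out <- matrix(NA_real_, n, nrow(v),
                dimnames = list(raw$sample_ids, v$variant_id))
  action <- character(nrow(v))
  amb_pair <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  for (k in seq_len(nrow(v))) {
    id <- v$variant_id[k]
    j <- match(id, raw$variant_ids)
    mi <- match(id, allele_map$variant_id)
    if (is.na(j) || is.na(mi)) {
      action[k] <- "absent"
      next
    }
    ref <- allele_map$ref[mi]; alt <- allele_map$alt[mi]
    if (alt == v$effect_allele[k] && ref == v$other_allele[k]) {
      out[, k] <- raw$dosages[, j]
      action[k] <- "ok"
    } else if (ref == v$effect_allele[k] && alt == v$other_allele[k]) {
      out[, k] <- 2 - raw$dosages[, j]
      action[k] <- "flipped"
    } else if (amb_pair(v$effect_allele[k], v$other_allele[k])) {
      action[k] <- "ambiguous"
      warnf("strand-ambiguous variant %s matches neither orientation; set missing", id)
    } else {
      action[k] <- "mismatch"
    }
  }
  if (!any(action %in% c("ok", "flipped"))) {
    stopf("no variants overlap between the source and the GRS definition")
  }
  g <- genotype_matrix(out)
  attr(g, "alignment_report") <- data.frame(
    variant_id = v$variant_id, action = action, stringsAsFactors = FALSE)
  g
}
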