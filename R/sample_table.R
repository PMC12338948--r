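#' Sample annotation tables
#'
#' A sample table carries, for every scored individual, a population label
#' drawn from a configured set and a disease status (`T1D` / `non_T1D`).
#'
#' @param sample_id character vector of unique ids.
#' @param population character vector of population labels.
#' @param status character vector of `"T1D"` / `"non_T1D"`.
#' @param allowed_populations optional label whitelist; defaults to the
#'   labels present.
#' @return A data.frame of class `sample_table`.
#' @export
sample_table <- function(sample_id, population, status,
                         allowed_populations = NULL) {
  d <- data.frame(sample_id = as.character(sample_id),
                  population = as.character(population),
                  status = as.character(status),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id)) {
    stopf("duplicate sample_id: %s",
          paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  allowed_populations <- allowed_populations %||% unique(d$population)
  bad_pop <- setdiff(unique(d$population), allowed_populations)
  if (length(bad_pop)) {
    stopf("unknown population label(s): %s (allowed: %s)",
          paste(bad_pop, collapse = ", "),
          paste(allowed_populations, collapse = ", "))
  }
  bad_st <- setdiff(unique(d$status), c("T1D", "non_T1D"))
  if (length(bad_st)) {
    stopf("unknown status token(s): %s (allowed: T1D, non_T1D)",
          paste(bad_st, collapse = ", "))
  }
  class(d) <- c("sample_table", "data.frame")
  attr(d, "allowed_populations") <- allowed_populations
  d
}

#' Read a sample table
#'
#' Tab-separated with header `sample_id`, `population`, `status`. Status
#' tokens outside `T1D`/`non_T1D` can be remapped through `status_map`
#' (e.g. `c(T2D = "non_T1D")` for cohorts whose controls are clinically
#' diagnosed type 2 diabetes).
#'
#' @param path file path.
#' @param allowed_populations character vector of legal population labels.
#' @param status_map optional named character vector mapping source tokens
#'   to `T1D`/`non_T1D`.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, allowed_populations = NULL,
                              status_map = NULL) {
  if (!file.exists(path)) stopf("sample table not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "population", "status"), names(d))
  if (length(need)) {
    stopf("sample table missing column(s): %s", paste(need, collapse = ", "))
  }
  if (!is.null(status_map)) {
    hit <- d$status %in% names(status_map)
    d$status[hit] <- unname(status_map[d$status[hit]])
  }
  sample_table(d$sample_id, d$population, d$status,
               allowed_populations = allowed_populations)
}

#' Write a sample table
#' @param samples a [sample_table()].
#' @param path output path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as.data.frame(samples)[c("sample_id", "population", "status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align a sample table to a score/genotype sample order; errors on mismatch.
match_samples <- function(samples, sample_ids) {
  i <- match(sample_ids, samples$sample_id)
  if (anyNA(i)) {
    stopf("sample(s) missing from the sample table: %s",
          paste(utils::head(sample_ids[is.na(i)], 5), collapse = ", "))
  }
  samples[i, , drop = FALSE]
}
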