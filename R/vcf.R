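#' Read genotype dosages from a VCF
#'
#' Extracts dosages for the wanted variants from a VCF 4.x file (plain or
#' bgzipped) carrying per-sample `GT` and/or `DS` fields. Records are
#' matched to wanted variants by chromosome and position; when both carry
#' an rsID a disagreement is reported as a warning (positions, not ids, are
#' authoritative). The per-sample dosage is the `DS` field when present,
#' otherwise the count of ALT alleles in `GT`. Multi-allelic records are
#' used only when a specific ALT allele, together with REF, matches the
#' wanted allele pair in either orientation; otherwise they are skipped
#' with a warning. Wanted variants not found are left out of the matrix
#' (and reported via the alleles map).
#'
#' @param path VCF path.
#' @param wanted a [grs_definition()] or a data.frame with `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`.
#' @return List: `genotypes` (a [genotype_matrix()] over the found
#'   variants, dosages counting the record's ALT allele) and `allele_map`
#'   (data.frame `variant_id`, `ref`, `alt`, `found`). Feed both to
#'   [align_genotypes()] to orient dosages to effect alleles.
#' @export
read_vcf_dosages <- function(path, wanted) {
  if (inherits(wanted, "grs_definition")) wanted <- wanted$variants
  wanted <- as.data.frame(wanted, stringsAsFactors = FALSE)
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  key <- paste(fix$CHROM, fix$POS)
  wkey <- paste(wanted$chrom, wanted$pos)
  hits <- lapply(wkey, function(k) which(key == k))
  n_hit <- lengths(hits)
  dup <- n_hit > 1
  if (any(dup)) {
    stopf("wanted variant appears more than once in the VCF at %s",
          paste(wkey[dup][1]))
  }

  samples <- colnames(vcf@gt)[-1]
  gt <- if (nrow(vcf@gt)) vcfR::extract.gt(vcf, element = "GT") else NULL
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)

  cols <- list(); map <- list()
  for (i in seq_len(nrow(wanted))) {
    if (n_hit[i] == 0L) {
      map[[i]] <- data.frame(variant_id = wanted$variant_id[i],
                             ref = NA_character_, alt = NA_character_,
                             found = FALSE, stringsAsFactors = FALSE)
      next
    }
    r <- hits[[i]]
    ref <- fix$REF[r]
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    if (!is.na(fix$ID[r]) && fix$ID[r] != "." &&
        fix$ID[r] != wanted$variant_id[i]) {
      warnf("rsID mismatch at %s: VCF has %s, definition has %s",
            wkey[i], fix$ID[r], wanted$variant_id[i])
    }
    pair_ok <- function(alt) {
      (ref == wanted$other_allele[i] && alt == wanted$effect_allele[i]) ||
        (ref == wanted$effect_allele[i] && alt == wanted$other_allele[i])
    }
    alt_idx <- which(vapply(alts, pair_ok, logical(1)))
    if (length(alts) > 1 && !length(alt_idx)) {
      warnf("multi-allelic record at %s matches no wanted allele pair; skipped",
            wkey[i])
      map[[i]] <- data.frame(variant_id = wanted$variant_id[i],
                             ref = NA_character_, alt = NA_character_,
                             found = FALSE, stringsAsFactors = FALSE)
      next
    }
    if (!length(alt_idx)) alt_idx <- 1L  # biallelic mismatch: report as-is
    alt <- alts[alt_idx[1]]
    dose <- NULL
    if (!is.null(ds) && !all(is.na(ds[r, ])) && length(alts) == 1L) {
      dose <- as.numeric(ds[r, ])
    }
    if (is.null(dose)) {
      if (is.null(gt)) stopf("VCF carries neither usable DS nor GT at %s", wkey[i])
      g <- gt[r, ]
      dose <- vapply(strsplit(g, "[/|]"), function(al) {
        if (!length(al) || any(is.na(al)) || any(al == ".")) return(NA_real_)
        sum(al == as.character(alt_idx[1]))
      }, numeric(1))
    }
    cols[[wanted$variant_id[i]]] <- dose
    map[[i]] <- data.frame(variant_id = wanted$variant_id[i],
                           ref = ref, alt = alt, found = TRUE,
                           stringsAsFactors = FALSE)
  }
  allele_map <- do.call(rbind, map)
  if (!length(cols)) stopf("none of the wanted variants were found in %s", path)
  m <- do.call(cbind, cols)
  rownames(m) <- samples
  list(genotypes = genotype_matrix(m), allele_map = allele_map)
}

#' Write a minimal VCF of dosages
#'
#' Emits a VCF 4.2 file with `GT:DS` per-sample fields (GT is `./.` for
#' non-integer dosages) with REF = the definition's other allele and ALT =
#' the effect allele, so a write/read round trip reproduces the matrix.
#'
#' @param g a [genotype_matrix()] aligned to `spec`.
#' @param spec a [grs_definition()] supplying chrom/pos/alleles.
#' @param path output path (plain text).
#' @export
write_vcf_dosages <- function(g, spec, path) {
  v <- spec$variants
  j <- match(v$variant_id, g$variant_ids)
  if (anyNA(j)) {
    stopf("variant(s) absent from genotype matrix: %s",
          paste(v$variant_id[is.na(j)], collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t")), con)
  ord <- order(v$chrom, v$pos)
  for (k in ord) {
    d <- g$dosages[, j[k]]
    gt <- ifelse(is.na(d) | abs(d - round(d)) > 1e-9, "./.",
                 c("0/0", "0/1", "1/1")[round(d) + 1])
    dss <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 10))
    writeLines(paste(c(v$chrom[k], v$pos[k], v$variant_id[k],
                       v$other_allele[k], v$effect_allele[k], ".", "PASS",
                       ".", "GT:DS", paste(gt, dss, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}
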