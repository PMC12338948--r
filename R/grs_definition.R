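#' GRS definition objects
#'
#' A `grs_definition` bundles everything needed to compute a genetic risk
#' score: the variant table (effect alleles and log-odds weights), the map
#' from DR-DQ haplotype names to their tag SNPs, the diplotype interaction
#' table, and any special combination rule (used by the 30-SNP score, where
#' two SNPs jointly tag DR3/DR4-DQ8 carriage).
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`, `region`
#'   (one of `hla_tag`, `hla_other`, `non_hla`), `role` (one of `linear`,
#'   `haplotype_tag`, `combination`) and `haplotype_name` (non-missing for
#'   `haplotype_tag` rows).
#' @param interactions optional data.frame with columns `hap_a`, `hap_b`,
#'   `weight`; pairs are unordered and any pair absent from the table has
#'   weight 0.
#' @param combinations optional data.frame with columns `geno_a`, `geno_b`,
#'   `weight`: a 9-cell lookup on the hard-called genotypes of the two
#'   `role = "combination"` variants (in variant-table order).
#' @param name score name; one of `"GRS1"`, `"GRS2"`, `"AAGRS"`, `"custom"`.
#'   The three named scores additionally enforce their published variant
#'   compositions (30/28/2, 67/14/53 with 21 + 32 linear split, 7/5/2).
#' @return An object of class `grs_definition`.
#' @seealso [load_grs_definition()], [grs_fixture()]
#' @export
grs_definition <- function(variants, interactions = NULL, combinations = NULL,
                           name = "custom") {
  obj <- structure(
    list(
      name = name,
      variants = as.data.frame(variants, stringsAsFactors = FALSE),
      interactions = if (!is.null(interactions)) {
        as.data.frame(interactions, stringsAsFactors = FALSE)
      } else {
        data.frame(hap_a = character(), hap_b = character(),
                   weight = numeric(), stringsAsFactors = FALSE)
      },
      combinations = if (!is.null(combinations)) {
        as.data.frame(combinations, stringsAsFactors = FALSE)
      } else {
        NULL
      }
    ),
    class = "grs_definition"
  )
  validate_grs_definition(obj)
}

GRS_REGIONS <- c("hla_tag", "hla_other", "non_hla")
GRS_ROLES <- c("linear", "haplotype_tag", "combination")

validate_grs_definition <- function(x) {
  v <- x$variants
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "weight", "region", "role")
  missing_cols <- setdiff(required, names(v))
  if (length(missing_cols)) {
    stopf("GRS definition is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!"haplotype_name" %in% names(v)) v$haplotype_name <- NA_character_
  v$haplotype_name[!is.na(v$haplotype_name) & v$haplotype_name == ""] <-
    NA_character_
  v$pos <- as.integer(v$pos)
  v$weight <- as.numeric(v$weight)

  if (anyDuplicated(v$variant_id)) {
    stopf("duplicate variant_id: %s",
          paste(unique(v$variant_id[duplicated(v$variant_id)]), collapse = ", "))
  }
  ok_allele <- function(a) {
    nzchar(a) & !is.na(a) & grepl("^[ACGT]+$", a)
  }
  bad <- !ok_allele(v$effect_allele) | !ok_allele(v$other_allele)
  if (any(bad)) {
    stopf("invalid alleles (must be non-empty strings over A/C/G/T) for: %s",
          paste(v$variant_id[bad], collapse = ", "))
  }
  same <- v$effect_allele == v$other_allele
  if (any(same)) {
    stopf("effect_allele equals other_allele for: %s",
          paste(v$variant_id[same], collapse = ", "))
  }
  if (any(!v$region %in% GRS_REGIONS)) {
    stopf("invalid region value(s): %s (field 'region')",
          paste(setdiff(unique(v$region), GRS_REGIONS), collapse = ", "))
  }
  if (any(!v$role %in% GRS_ROLES)) {
    stopf("invalid role value(s): %s (field 'role')",
          paste(setdiff(unique(v$role), GRS_ROLES), collapse = ", "))
  }
  lin <- v$role == "linear"
  if (any(lin & !is.finite(v$weight))) {
    stopf("non-finite weight for linear variant(s): %s (field 'weight')",
          paste(v$variant_id[lin & !is.finite(v$weight)], collapse = ", "))
  }
  # Tag SNPs contribute only through the interaction table.
  tag <- v$role == "haplotype_tag"
  if (any(tag & is.finite(v$weight) & v$weight != 0)) {
    stopf("haplotype_tag variant(s) must carry no linear weight: %s",
          paste(v$variant_id[tag & v$weight != 0], collapse = ", "))
  }
  v$weight[tag] <- 0
  if (any(tag & is.na(v$haplotype_name))) {
    stopf("haplotype_tag variant(s) missing haplotype_name: %s",
          paste(v$variant_id[tag & is.na(v$haplotype_name)], collapse = ", "))
  }
  if (anyDuplicated(v$haplotype_name[tag])) {
    stopf("duplicate haplotype_name among tag variants")
  }

  it <- x$interactions
  if (nrow(it)) {
    need <- setdiff(c("hap_a", "hap_b", "weight"), names(it))
    if (length(need)) {
      stopf("interaction table missing column(s): %s",
            paste(need, collapse = ", "))
    }
    it$weight <- as.numeric(it$weight)
    if (any(!is.finite(it$weight))) {
      stopf("non-finite interaction weight (field 'weight')")
    }
    haps <- v$haplotype_name[tag]
    unknown <- setdiff(unique(c(it$hap_a, it$hap_b)), haps)
    if (length(unknown)) {
      stopf("interaction pair references unknown haplotype(s): %s",
            paste(unknown, collapse = ", "))
    }
    key <- pair_key(it$hap_a, it$hap_b)
    if (anyDuplicated(key)) {
      stopf("duplicate (unordered) interaction pair(s): %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))
    }
  }

  cb <- x$combinations
  comb_idx <- which(v$role == "combination")
  if (!is.null(cb)) {
    need <- setdiff(c("geno_a", "geno_b", "weight"), names(cb))
    if (length(need)) {
      stopf("combination rule missing column(s): %s", paste(need, collapse = ", "))
    }
    if (length(comb_idx) != 2L) {
      stopf("a combination rule requires exactly 2 role=combination variants (found %d)",
            length(comb_idx))
    }
    cb$geno_a <- as.integer(cb$geno_a); cb$geno_b <- as.integer(cb$geno_b)
    cb$weight <- as.numeric(cb$weight)
    if (nrow(cb) != 9L ||
        !setequal(paste(cb$geno_a, cb$geno_b),
                  paste(rep(0:2, each = 3), rep(0:2, 3)))) {
      stopf("combination rule must cover the 9 genotype cells (0-2 x 0-2)")
    }
    if (any(!is.finite(cb$weight))) stopf("non-finite combination weight")
  } else if (length(comb_idx)) {
    stopf("role=combination variants present but no combination rule supplied")
  }

  x$variants <- v
  x$interactions <- it
  x$combinations <- cb
  check_named_composition(x)
  x
}

# The three published scores have fixed printed compositions; enforce them
# whenever a definition claims one of the names.
check_named_composition <- function(x) {
  v <- x$variants
  n_tag <- sum(v$role == "haplotype_tag")
  n_lin <- sum(v$role == "linear")
  n_comb <- sum(v$role == "combination")
  if (identical(x$name, "GRS2")) {
    if (nrow(v) != 67L || n_tag != 14L || n_lin != 53L ||
        sum(v$role == "linear" & v$region == "hla_other") != 21L ||
        sum(v$role == "linear" & v$region == "non_hla") != 32L ||
        nrow(x$interactions) != 18L) {
      stopf(paste0("GRS2 composition must be 67 variants = 14 DR-DQ tags + ",
                   "21 HLA + 32 non-HLA linear SNPs, with 18 interaction pairs"))
    }
  } else if (identical(x$name, "GRS1")) {
    if (nrow(v) != 30L || n_lin != 28L || n_comb != 2L) {
      stopf("GRS1 composition must be 30 variants = 28 linear + 2 combination")
    }
  } else if (identical(x$name, "AAGRS")) {
    n_hla <- sum(v$region %in% c("hla_tag", "hla_other"))
    if (nrow(v) != 7L || n_lin != 7L || n_hla != 5L ||
        sum(v$region == "non_hla") != 2L) {
      stopf("AAGRS composition must be 7 linear variants (5 HLA + 2 non-HLA)")
    }
  }
  invisible(x)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Load a GRS definition from tab-separated files
#'
#' The main file has columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `weight`, `region`, `role`, `haplotype_name`. An optional
#' companion interaction file (`hap_a`, `hap_b`, `weight`) supplies DR-DQ
#' diplotype weights; an optional combination-rule file (`geno_a`, `geno_b`,
#' `weight`) supplies the 9-cell genotype lookup used by GRS1.
#'
#' @param path path to the variant table.
#' @param interactions_path optional path to the interaction table.
#' @param combinations_path optional path to the combination rule.
#' @param name score name (`"GRS1"`, `"GRS2"`, `"AAGRS"`, or `"custom"`).
#' @return A validated [grs_definition()].
#' @export
load_grs_definition <- function(path, interactions_path = NULL,
                                combinations_path = NULL, name = "custom") {
  if (!file.exists(path)) stopf("GRS definition file not found: %s", path)
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!is.numeric(v$weight) && !all(is.na(v$weight))) {
    stopf("non-numeric value in field 'weight' of %s", path)
  }
  if (any(is.nan(v$weight))) {
    stopf("NaN value in field 'weight' of %s", path)
  }
  it <- NULL
  if (!is.null(interactions_path)) {
    if (!file.exists(interactions_path)) {
      stopf("interaction file not found: %s", interactions_path)
    }
    it <- utils::read.delim(interactions_path, stringsAsFactors = FALSE)
  }
  cb <- NULL
  if (!is.null(combinations_path)) {
    if (!file.exists(combinations_path)) {
      stopf("combination-rule file not found: %s", combinations_path)
    }
    cb <- utils::read.delim(combinations_path, stringsAsFactors = FALSE)
  }
  grs_definition(v, interactions = it, combinations = cb, name = name)
}

#' Packaged GRS definition fixtures
#'
#' Loads one of the definitions shipped with the package. The `grs1`, `grs2`
#' and `aagrs` fixtures are *synthetic stand-ins*: they reproduce the exact
#' published compositions of the corresponding scores (30 SNPs with 28 linear
#' and a 2-SNP DR3/DR4-DQ8 combination rule; 67 SNPs with 14 DR-DQ tags, 18
#' diplotype interaction pairs and a 21 + 32 HLA/non-HLA linear split; 7 SNPs
#' with 5 HLA and 2 non-HLA, anchored on rs2187668 and rs9273363) with
#' realistic log-odds magnitudes, but the weights are not transcriptions of
#' the published supplementary tables. `toy` is a small definition (6 linear
#' variants, 3 tagged haplotypes, 3 interaction pairs) used throughout the
#' test suite.
#'
#' @param name one of `"grs1"`, `"grs2"`, `"aagrs"`, `"toy"`.
#' @return A [grs_definition()].
#' @export
grs_fixture <- function(name = c("grs2", "grs1", "aagrs", "toy")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "grsxpop",
                                  mustWork = TRUE)
  switch(name,
    grs2 = load_grs_definition(path("grs2_synthetic.tsv"),
                               interactions_path = path("grs2_synthetic_interactions.tsv"),
                               name = "GRS2"),
    grs1 = load_grs_definition(path("grs1_synthetic.tsv"),
                               combinations_path = path("grs1_synthetic_combination.tsv"),
                               name = "GRS1"),
    aagrs = load_grs_definition(path("aagrs_synthetic.tsv"), name = "AAGRS"),
    toy = load_grs_definition(path("toy.tsv"),
                              interactions_path = path("toy_interactions.tsv"),
                              name = "custom")
  )
}

#' @export
print.grs_definition <- function(x, ...) {
  v <- x$variants
  cat(sprintf("<grs_definition> %s: %d variants (%d linear, %d haplotype tags, %d combination)\n",
              x$name, nrow(v), sum(v$role == "linear"),
              sum(v$role == "haplotype_tag"), sum(v$role == "combination")))
  if (nrow(x$interactions)) {
    cat(sprintf("  %d DR-DQ interaction pairs\n", nrow(x$interactions)))
  }
  if (!is.null(x$combinations)) cat("  2-SNP combination rule attached\n")
  invisible(x)
}

# Named haplotype -> tag variant_id map.
haplotype_tags <- function(spec) {
  v <- spec$variants
  tag <- v$role == "haplotype_tag"
  stats::setNames(v$variant_id[tag], v$haplotype_name[tag])
}

# Interaction weight lookup for unordered haplotype pairs; pairs not in the
# table (and anything involving OTHER) score 0.
interaction_lookup <- function(spec) {
  it <- spec$interactions
  stats::setNames(it$weight, pair_key(it$hap_a, it$hap_b))
}
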