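#' Run the full cross-ancestry evaluation pipeline
#'
#' Orchestrates simulate/read -> score -> evaluate -> crosspop ->
#' mixed-controls -> combine -> importance behind one configuration object,
#' writing per-stage TSV/JSON outputs plus a reproducibility manifest
#' (inputs, seeds, package version, output checksums) into one run
#' directory. Re-running the same configuration reproduces all outputs
#' byte-identically.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   elements:
#'   \describe{
#'     \item{out_dir}{output directory (created).}
#'     \item{stages}{character subset of `simulate`, `score`, `evaluate`,
#'       `crosspop`, `mixed_controls`, `combine`, `importance`; stage
#'       dependencies are checked before anything runs.}
#'     \item{scenario}{`"builtin:five_pop"` to simulate, or omit and supply
#'       `dosage_path`/`sample_path` for real input tables.}
#'     \item{grs}{character vector of packaged definition names
#'       (`grs2`, `grs1`, `aagrs`, `toy`); first entry drives the
#'       population-level analyses.}
#'     \item{seed}{master integer seed.}
#'     \item{boot_reps}{bootstrap replicates for AUC intervals
#'       (default 500).}
#'     \item{threshold}{shared risk threshold for the confusion report
#'       (default: pooled median score of the primary GRS).}
#'     \item{grid_points}{number of points in the sensitivity/specificity
#'       threshold grid (default 41).}
#'     \item{mixed_case_pop}{case population for the mixed-control analysis
#'       (default: first population).}
#'   }
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stages <- config$stages %||% c("simulate", "score", "evaluate", "crosspop",
                                 "mixed_controls", "combine", "importance")
  all_stages <- c("simulate", "score", "evaluate", "crosspop",
                  "mixed_controls", "combine", "importance")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  needs_input <- setdiff(stages, "simulate")
  has_input <- "simulate" %in% stages ||
    (!is.null(config$dosage_path) && !is.null(config$sample_path))
  if (length(needs_input) && !has_input) {
    stopf("config error: stages %s need either the simulate stage or dosage_path/sample_path",
          paste(needs_input, collapse = ", "))
  }
  downstream <- intersect(stages, c("evaluate", "crosspop", "mixed_controls",
                                    "combine", "importance"))
  if (length(downstream) && !"score" %in% stages) {
    stopf("config error: stage(s) %s require the score stage",
          paste(downstream, collapse = ", "))
  }
  out_dir <- config$out_dir %||% stopf("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  boot_reps <- config$boot_reps %||% 500L
  grs_names <- config$grs %||% "grs2"

  specs <- lapply(grs_names, grs_fixture)
  names(specs) <- grs_names
  outputs <- character(0)
  emit <- function(obj, fname) {
    p <- file.path(out_dir, fname)
    if (is.data.frame(obj) || is.matrix(obj)) {
      utils::write.table(as.data.frame(obj), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs -------------------------------------------------------------
  if ("simulate" %in% stages) {
    scenario <- config$scenario %||% "builtin:five_pop"
    if (!identical(scenario, "builtin:five_pop")) {
      stopf("only the builtin:five_pop scenario is bundled; got '%s'", scenario)
    }
    suite <- default_five_population_suite(specs[[1]], seed = seed)
    data <- bind_populations(suite)
    emit(data.frame(sample_id = data$genotypes$sample_ids,
                    data$genotypes$dosages, check.names = FALSE),
         "dosages.tsv")
    emit(as.data.frame(data$samples), "samples.tsv")
  } else {
    data <- list(genotypes = read_dosage_table(config$dosage_path),
                 samples = read_sample_table(config$sample_path))
  }
  samples <- match_samples(data$samples, data$genotypes$sample_ids)
  labels <- samples$status
  pops <- unique(samples$population)

  results <- list()
  if ("score" %in% stages) {
    results$scores <- lapply(specs, function(sp) {
      sub <- subset_to_spec(data$genotypes, sp)
      score(sub, sp)
    })
    for (nm in names(results$scores)) {
      emit(as.data.frame(results$scores[[nm]]), sprintf("scores_%s.tsv", nm))
    }
  }
  primary <- if ("score" %in% stages) results$scores[[1]] else NULL

  if ("evaluate" %in% stages) {
    seeds <- derive_seeds(seed + 1L, length(specs) * length(pops))
    si <- 0L
    auc_rows <- list()
    for (nm in names(results$scores)) {
      sc <- results$scores[[nm]]$total
      for (p in pops) {
        si <- si + 1L
        sel <- samples$population == p
        rr <- roc_result(sc[sel], labels[sel], n_reps = boot_reps,
                         seed = seeds[si])
        emit(rr$points, sprintf("roc_%s_%s.tsv", nm, p))
        auc_rows[[length(auc_rows) + 1L]] <- data.frame(
          grs = nm, population = p, auc = rr$auc, ci_low = rr$ci_low,
          ci_high = rr$ci_high, n_cases = rr$n_cases,
          n_controls = rr$n_controls, stringsAsFactors = FALSE)
      }
    }
    auc_tab <- do.call(rbind, auc_rows)
    emit(auc_tab, "auc_summary.tsv")
    thr <- config$threshold %||% stats::median(primary$total)
    grid <- seq(min(primary$total), max(primary$total),
                length.out = config$grid_points %||% 41L)
    emit(sens_spec_curve(primary$total, labels, samples$population, grid),
         "sens_spec_curves.tsv")
    emit(threshold_report(primary$total, labels, samples$population, thr),
         "threshold_report.tsv")
  }

  if ("crosspop" %in% stages) {
    dm <- crosspop_delta_matrix(stats::setNames(primary$total,
                                                primary$sample_id), samples)
    emit(as.data.frame(dm), "crosspop_delta.tsv")
  }

  if ("mixed_controls" %in% stages) {
    case_pop <- config$mixed_case_pop %||% pops[1]
    score_list <- lapply(results$scores, function(s)
      stats::setNames(s$total, s$sample_id))
    emit(mixed_control_auc(score_list, samples, case_pop,
                           seed = derive_seeds(seed + 2L, 1L)),
         "mixed_controls.tsv")
  }

  if ("combine" %in% stages) {
    if (length(results$scores) >= 2) {
      cmb <- optimal_weighted_sum(results$scores[[1]], results$scores[[2]],
                                  labels, grid_step = config$grid_step %||% 0.01)
      emit(list(method = cmb$method, weight = cmb$weight, auc = cmb$auc,
                auc_components = as.list(cmb$auc_components),
                in_sample = cmb$in_sample),
           "combine_opt_summed.json")
      emit(data.frame(grs = names(results$scores)[1:2],
                      auc_alone = unname(cmb$auc_components),
                      stringsAsFactors = FALSE),
           "combine_components.tsv")
      corr <- grs_correlations(results$scores)
      emit(data.frame(grs = rownames(corr), corr, check.names = FALSE),
           "grs_correlations.tsv")
    }
  }

  if ("importance" %in% stages) {
    for (nm in names(results$scores)) {
      sp <- specs[[nm]]
      sub <- subset_to_spec(data$genotypes, sp)
      emit(snp_importance(sub, sp, samples,
                          interaction = results$scores[[nm]]$interaction),
           sprintf("importance_%s.tsv", nm))
    }
  }

  manifest <- list(
    package = "grsxpop",
    version = as.character(utils::packageVersion("grsxpop")),
    created = "run manifest",
    config = config[setdiff(names(config), "out_dir")],
    seed = seed,
    stages = stages,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Column-subset a genotype matrix to a definition's variants.
subset_to_spec <- function(g, spec) {
  j <- match(spec$variants$variant_id, g$variant_ids)
  if (anyNA(j)) {
    stopf("genotype matrix lacks variant(s) of %s: %s", spec$name,
          paste(utils::head(spec$variants$variant_id[is.na(j)], 5),
                collapse = ", "))
  }
  genotype_matrix(g$dosages[, j, drop = FALSE])
}
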