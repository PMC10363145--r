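## End-to-end orchestration: preprocess -> module filter -> DIRAC ->
## statistics (-> flux screening/enrichment), with all results persisted as
## TSV plus a JSON run summary. Outputs carry no timestamps, so a rerun
## with identical inputs and config is byte-identical.

#' Write pipeline results to a directory
#'
#' Persists the standard result tables: long-form RMS, group x module RCI,
#' per-module statistics (ANOVA + post hoc), cross-consensus similarity,
#' module-filter audit, and - when the flux stage ran - the reaction
#' screen, per-subsystem enrichment and scaled mean-change matrix; plus
#' `summary.json` with the configuration, seed and per-table row counts.
#'
#' @param results A `dirac_pipeline` result from [run_pipeline()].
#' @param out_dir Output directory (created if needed; must be writable).
#' @param overwrite Allow replacing existing result files.
#' @return Invisibly, the named vector of written paths.
#' @export
write_results <- function(results, out_dir, overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    fail("output directory '%s' is not writable", out_dir)
  }
  tables <- list(rms = results$dirac$rms,
                 rci = results$dirac$rci,
                 module_stats = results$module_stats,
                 similarity = results$similarity,
                 module_audit = results$module_audit,
                 overall_shift = results$overall_shift,
                 flux_screen = results$flux_screen,
                 flux_enrichment = results$flux_enrichment)
  tables <- Filter(Negate(is.null), tables)
  paths <- stats::setNames(file.path(out_dir, paste0(names(tables), ".tsv")),
                           names(tables))
  json_path <- file.path(out_dir, "summary.json")
  existing <- c(paths, json_path)[file.exists(c(paths, json_path))]
  if (length(existing) && !overwrite) {
    fail("output file(s) already exist (use overwrite = TRUE): %s",
         paste(existing, collapse = ", "))
  }
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(results$scaled_change)) {
    p <- file.path(out_dir, "flux_scaled_change.tsv")
    write_abundance(abundance_table(results$scaled_change), p,
                    id_column = "reaction_id")
    paths <- c(paths, scaled_change = p)
  }
  summary <- list(config = results$config,
                  seed = results$config$seed,
                  stages = results$stages,
                  counts = c(lapply(tables, nrow),
                             list(summary_sets = results$summary$counts)))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, summary = json_path))
}

#' Run the full rank-conservation pipeline
#'
#' Executes the fixed stage order - preprocessing (covariate regression,
#' complete-case filter, robust Z-scores), module coverage filtering, DIRAC
#' scoring under every group's consensus, the tightening/similarity
#' statistics, and optionally the flux screening/enrichment stage - and, if
#' `out_dir` is given, persists every table with [write_results()].
#'
#' Inputs may be in-memory objects or file paths (TSV/GMT), so any stage's
#' outputs can be inspected and the run reproduced from files alone.
#'
#' @param abundance [abundance_table()] or TSV path.
#' @param metadata [sample_metadata()] or TSV path.
#' @param modules Annotation [module_set()] or GMT path.
#' @param control Control group label.
#' @param interventions Intervention labels (default: all non-control
#'   groups).
#' @param flux Optional [flux_table()] or flux TSV path.
#' @param subsystems Optional subsystem-map TSV path (when `flux` is a
#'   path).
#' @param flux_metadata Metadata for the flux samples (defaults to
#'   `metadata`).
#' @param alpha Post-hoc / similarity significance threshold.
#' @param fdr_alpha ANOVA FDR gate threshold.
#' @param consistency MAD consistency flag (see [robust_mad()]).
#' @param skip_covariates Skip the sex/age regression.
#' @param control_reference Apply the per-analyte control-referenced
#'   Z-score (see [preprocess_abundance()]); disable for calibration runs.
#' @param out_dir Optional output directory.
#' @param overwrite Passed to [write_results()].
#' @param seed Recorded in the run summary (the analysis itself is
#'   deterministic).
#' @return A `dirac_pipeline` list: `preprocess_report`, `module_audit`,
#'   `modules`, `dirac`, `overall_shift`, `module_stats`, `similarity`,
#'   `summary`, and when flux was supplied `flux_screen`,
#'   `flux_enrichment`, `scaled_change`; plus `config` and `stages`.
#' @export
run_pipeline <- function(abundance, metadata, modules, control,
                         interventions = NULL, flux = NULL,
                         subsystems = NULL, flux_metadata = NULL,
                         alpha = 0.05, fdr_alpha = 0.05,
                         consistency = FALSE, skip_covariates = FALSE,
                         control_reference = TRUE,
                         out_dir = NULL, overwrite = FALSE, seed = NULL) {
  check_alpha(alpha)
  check_alpha(fdr_alpha, "fdr_alpha")
  stage <- function(name) dlog("pipeline stage: %s", name)

  stage("load")
  if (is.character(abundance)) abundance <- read_abundance(abundance)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(modules)) modules <- read_gmt(modules)
  if (is.character(flux)) flux <- read_flux(flux, subsystem_path = subsystems)
  if (is.null(flux_metadata)) flux_metadata <- metadata
  groups <- unique(metadata$group[metadata$sample_id %in% colnames(abundance)])
  if (!control %in% groups) {
    fail("control group '%s' not present in the data", control)
  }
  if (is.null(interventions)) interventions <- setdiff(groups, control)
  unknown <- setdiff(interventions, groups)
  if (length(unknown)) {
    fail("intervention group(s) not present in the data: %s",
         paste(unknown, collapse = ", "))
  }
  stages <- c("load")

  stage("preprocess")
  prep <- preprocess_abundance(abundance, metadata, control,
                               consistency = consistency,
                               skip_covariates = skip_covariates,
                               control_reference = control_reference)
  stages <- c(stages, "preprocess")

  stage("modules")
  filt <- build_filtered_modules(modules, rownames(prep$table))
  if (!length(filt$modules$members)) {
    fail("no module survives the coverage filter")
  }
  stages <- c(stages, "modules")

  stage("dirac")
  dr <- dirac_rms(prep$table, metadata, filt$modules,
                  consensus_groups = c(control, interventions))
  stages <- c(stages, "dirac")

  stage("stats")
  shift <- overall_rci_shift(dr$rci, control, interventions)
  anova <- module_anova(dr$rms, groups = c(control, interventions))
  pass <- anova$module_id[anova$p_adj < fdr_alpha]
  posthoc <- posthoc_tightening(dr$rms, control, interventions,
                                anova_pass = pass, alpha = alpha)
  similarity <- cross_consensus_similarity(dr$rms, control, interventions,
                                           consensus_groups = interventions,
                                           alpha = alpha)
  summary_sets <- consistent_tightening_summary(posthoc, similarity,
                                                interventions)
  module_stats <- merge(anova, posthoc, by = "module_id", all.x = TRUE,
                        sort = TRUE, suffixes = c("_anova", "_posthoc"))
  stages <- c(stages, "stats")

  res <- list(preprocess_report = prep$report,
              module_audit = filt$audit,
              modules = filt$modules,
              dirac = dr,
              overall_shift = shift,
              anova = anova,
              posthoc = posthoc,
              module_stats = module_stats,
              similarity = similarity,
              summary = summary_sets)

  if (!is.null(flux)) {
    stage("flux")
    func <- filter_functional_reactions(flux)
    screen <- screen_changed_reactions(func, flux_metadata, control,
                                       interventions, alpha = alpha)
    enrich <- do.call(rbind, lapply(interventions, function(g) {
      e <- subsystem_enrichment(screen, g)
      if (nrow(e)) cbind(intervention = g, e) else NULL
    }))
    if (is.null(enrich)) {
      enrich <- data.frame(intervention = character(0),
                           subsystem = character(0), k = integer(0),
                           K = integer(0), n = integer(0), N = integer(0),
                           p = numeric(0), p_adj = numeric(0))
    }
    res$flux_screen <- screen
    res$flux_enrichment <- enrich
    res$scaled_change <- scaled_mean_change(func, flux_metadata, control,
                                            interventions)
    stages <- c(stages, "flux")
  }

  res$config <- list(control = control, interventions = interventions,
                     alpha = alpha, fdr_alpha = fdr_alpha,
                     consistency = consistency,
                     skip_covariates = skip_covariates,
                     control_reference = control_reference, seed = seed)
  res$stages <- stages
  class(res) <- "dirac_pipeline"

  if (!is.null(out_dir)) write_results(res, out_dir, overwrite = overwrite)
  res
}

#' @export
print.dirac_pipeline <- function(x, ...) {
  cat(sprintf(paste0("dirac_pipeline: %d modules, %d RMS rows; ",
                     "%d ANOVA-significant, tightened by all: %d ",
                     "(similar: %d)\n"),
              length(x$modules$members), nrow(x$dirac$rms),
              sum(x$anova$p_adj < x$config$fdr_alpha),
              length(x$summary$tightened_all),
              length(x$summary$tightened_all_similar)))
  invisible(x)
}
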