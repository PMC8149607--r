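#' Run the full twin methylome pipeline on a simulated cohort
#'
#' Orchestrates simulate -> filter -> DMS -> DMR -> (optional) annotate ->
#' twin-similarity statistics as one deterministic run. All stages are
#' pure functions of the simulated cohort, so a given `config` and `seed`
#' always produce identical results.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param genes Optional gene-model tibble for annotation.
#' @param candidates Optional candidate gene names for over-representation.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV together with a run manifest.
#' @param min_reads,max_strand_delta QC filter settings.
#' @param delta_min,cv_max DMS thresholds.
#' @param dmr_args Named list of overrides passed to [call_dmrs()].
#' @return List of class `twin_pipeline` with elements `cohort`,
#'   `filtered`, `dms`, `dms_score`, `dmrs`, `dmrs_group`, `dmr_score`,
#'   `correlations`, `correlations_masked`, `ks`, `conversion`,
#'   `annotated`, `enrichment`, `manifest`.
#' @export
run_twin_pipeline <- function(config = sim_config(), seed = 1,
                              genes = NULL, candidates = NULL,
                              out_dir = NULL,
                              min_reads = 20, max_strand_delta = 0.20,
                              delta_min = 0.30, cv_max = 0.25,
                              dmr_args = list()) {
  cohort <- simulate_twin_cohort(config, seed)
  filtered <- filter_cohort(cohort$counts, min_reads = min_reads,
                            max_strand_delta = max_strand_delta,
                            blacklist = cohort$blacklist)
  dms <- call_dms(filtered$beta, cohort$meta,
                  delta_min = delta_min, cv_max = cv_max)
  dms_score <- score_dms_calls(dms, cohort$truth, cohort$vmr)
  dmrs <- do.call(call_dmrs, c(list(filtered$counts, cohort$meta,
                                    mode = "pairwise"), dmr_args))
  dmrs_group <- do.call(call_dmrs, c(list(filtered$counts, cohort$meta,
                                          mode = "groupwise"), dmr_args))
  dmr_score <- score_dmr_calls(dmrs, cohort$truth,
                               distinct(filtered$beta, .data$chrom, .data$pos))

  scheme <- build_pairing_scheme(cohort$meta)
  correlations <- pairwise_correlation(filtered$beta, scheme)
  beta_masked <- mask_intervals(filtered$beta, cohort$vmr, "remove")
  correlations_masked <- pairwise_correlation(beta_masked, scheme)
  ks <- ks_two_sample(abs_diff_profile(filtered$beta, scheme, "co-twin"),
                      abs_diff_profile(filtered$beta, scheme, "unrelated"))
  conversion <- conversion_efficiency(cohort$lambda$converted,
                                      cohort$lambda$unconverted)

  annotated <- enrichment <- NULL
  if (!is.null(genes)) {
    hits <- filter(dms, .data$passes)
    annotated <- annotate_hits(hits, genes)
    if (!is.null(candidates)) {
      annotated <- candidate_overlap(annotated, candidates)
      enrichment <- enrichment_by_pair(annotated, genes$name, candidates)
    }
  }

  manifest <- tibble(
    stage = c("simulate", "filter", "dms", "dmr_pairwise", "dmr_groupwise"),
    n_rows = c(nrow(cohort$counts), nrow(filtered$beta),
               sum(dms$passes), nrow(dmrs), nrow(dmrs_group)),
    seed = seed
  )

  out <- structure(
    list(cohort = cohort, filtered = filtered, dms = dms,
         dms_score = dms_score, dmrs = dmrs, dmrs_group = dmrs_group,
         dmr_score = dmr_score, correlations = correlations,
         correlations_masked = correlations_masked, ks = ks,
         conversion = conversion, annotated = annotated,
         enrichment = enrichment, manifest = manifest),
    class = "twin_pipeline")

  if (!is.null(out_dir)) write_pipeline_tables(out, out_dir)
  out
}

#' @export
print.twin_pipeline <- function(x, ...) {
  cat("twin_pipeline run (seed", x$manifest$seed[1], ")\n")
  cat(sprintf("  retained sites: %d\n", nrow(x$filtered$beta)))
  cat(sprintf("  DMS calls: %d (sensitivity %.3f, FDP %.3f)\n",
              sum(x$dms$passes), x$dms_score$sensitivity, x$dms_score$fdp))
  cat(sprintf("  DMRs: %d pairwise, %d groupwise (recovered %d/%d testable)\n",
              nrow(x$dmrs), nrow(x$dmrs_group),
              x$dmr_score$n_recovered, x$dmr_score$n_testable))
  cat(sprintf("  conversion efficiency: %.4f\n", x$conversion))
  invisible(x)
}

# write all result tables + manifest as TSV
write_pipeline_tables <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    df <- dplyr::select(df, -dplyr::any_of("member_positions"))
    readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
  }
  write_beta_matrix(res$filtered$beta, file.path(out_dir, "beta_matrix.tsv"))
  w(filter(res$dms, .data$passes), "dms")
  w(res$dmrs, "dmr_pairwise")
  w(res$dmrs_group, "dmr_groupwise")
  w(res$correlations$pairs, "correlation_pairs")
  w(res$correlations$summary, "correlation_summary")
  w(res$annotated, "annotated")
  w(res$enrichment, "enrichment")
  w(res$manifest, "manifest")
  invisible(out_dir)
}

#' Read a pipeline run configuration file
#'
#' YAML file with any subset of the [sim_config()] fields plus optional
#' top-level `seed`, `min_reads`, `max_strand_delta`, `delta_min`,
#' `cv_max`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return List with elements `config` (a `sim_config`) and the run
#'   settings.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_keys <- c("seed", "min_reads", "max_strand_delta", "delta_min",
                "cv_max")
  sim_keys <- names(formals(sim_config))
  unknown <- setdiff(names(raw), c(run_keys, sim_keys))
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg <- do.call(sim_config, raw[intersect(names(raw), sim_keys)])
  c(list(config = cfg), raw[intersect(names(raw), run_keys)])
}
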