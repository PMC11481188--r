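#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage end to end: cohort simulation, low-count filtering and
#' TMM normalization, co-expression module detection with age screening,
#' per-transcript trajectory fitting and model selection, direction
#' assignment, directional pathway enrichment, pathway tipping points,
#' staining onset estimation, and timeline assembly. All randomness flows
#' from `seed`, so two runs with the same arguments produce byte-identical
#' output files.
#'
#' @param out_dir Output directory; inputs are written under
#'   `<out_dir>/input`, results under `<out_dir>/output`. `NULL` skips all
#'   file output.
#' @param seed Master seed.
#' @param n_samples Cohort size.
#' @param module_plan Planted module plan (see [default_module_plan()]).
#' @param min_total Low-count filter threshold.
#' @param power,min_module_size,deep_split,merge_threshold Network-stage
#'   parameters.
#' @param alpha Significance level shared by the F test, enrichment and
#'   module screening.
#' @param epsilon Fast-window tolerance for the staining fit.
#' @param fit_scope Which transcripts get trajectory fits:
#'   `"significant"` (default) restricts to members of significantly
#'   age-correlated modules, mirroring the screening convention;
#'   `"assigned"` fits every module member, which is the right scope when
#'   measuring planted-truth recovery (the eigengene-age screen is itself
#'   noisy, since a module's shared non-age variation can mask its trend).
#' @return Invisibly, a list with every intermediate result: `cohort`,
#'   `normalized`, `modules`, `fits`, `directions`, `enrichment`,
#'   `tipping_points`, `onset`, `timeline`.
#' @export
run_pipeline <- function(out_dir = NULL, seed = 1L, n_samples = 35L,
                         module_plan = default_module_plan(),
                         min_total = 30, power = 12, min_module_size = 30,
                         deep_split = 2, merge_threshold = 0.25,
                         alpha = 0.05, epsilon = 0.02,
                         fit_scope = c("significant", "assigned")) {
  fit_scope <- match.arg(fit_scope)
  cohort <- simulate_cohort(n_samples = n_samples, seed = seed,
                            module_plan = module_plan)
  norm <- preprocess_counts(cohort$expression$counts, min_total = min_total)
  modules <- find_modules(norm, cohort$ages, power = power,
                          min_module_size = min_module_size,
                          deep_split = deep_split,
                          merge_threshold = merge_threshold, alpha = alpha)

  sig_mods <- if (is.null(modules$age_stats)) character(0) else
    modules$age_stats$module[modules$age_stats$significant]
  in_scope <- if (fit_scope == "significant")
    paste0("M", modules$labels) %in% sig_mods
  else modules$labels > 0
  scaled <- scale_per_transcript(norm$matrix)
  fit_ids <- names(modules$labels)[in_scope]
  fits <- if (length(fit_ids) > 0)
    fit_trajectories(scaled[fit_ids, , drop = FALSE], cohort$ages,
                     alpha = alpha)
  else NULL

  directions <- if (!is.null(fits))
    assign_directions(modules$labels[fit_ids], modules$age_stats, fits)
  else NULL
  enrichment <- if (!is.null(directions) && nrow(directions) > 0)
    pathway_enrichment(directions, cohort$pathways,
                       universe_genes = rownames(norm$matrix), alpha = alpha)
  else NULL

  tipping <- list()
  if (!is.null(fits)) {
    for (nm in names(cohort$pathways)) {
      tp <- withCallingHandlers(
        pathway_tipping_point(fits, cohort$pathways[[nm]]),
        warning = function(w) invokeRestart("muffleWarning"))
      if (tp$n_members > 0) tipping[[nm]] <- tp
    }
  }

  onset <- estimate_onset(cohort$staining, epsilon = epsilon)
  timeline <- build_timeline(tipping, staining = onset)

  res <- list(cohort = cohort, normalized = norm, modules = modules,
              fits = fits, directions = directions, enrichment = enrichment,
              tipping_points = tipping, onset = onset, timeline = timeline)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

# Deterministic plain-text serialization of a pipeline run.
write_pipeline_outputs <- function(res, out_dir) {
  in_dir <- file.path(out_dir, "input")
  o <- file.path(out_dir, "output")
  dir.create(o, recursive = TRUE, showWarnings = FALSE)
  write_cohort(res$cohort, in_dir)

  tsv <- function(df, name) write.table(df, file.path(o, name), sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  tsv(data.frame(sample_id = colnames(res$normalized$matrix),
                 tmm_factor = res$normalized$scaling_factors,
                 lib_size = res$normalized$lib_sizes), "tmm_factors.tsv")
  tsv(data.frame(transcript_id = names(res$modules$labels),
                 module_id = unname(res$modules$labels)), "module_labels.tsv")
  if (!is.null(res$modules$age_stats)) {
    tsv(res$modules$age_stats, "module_age_stats.tsv")
    tsv(data.frame(sample_id = rownames(res$modules$eigengenes),
                   res$modules$eigengenes, check.names = FALSE),
        "eigengenes.tsv")
  }
  if (!is.null(res$fits)) tsv(res$fits, "trajectory_fits.tsv")
  if (!is.null(res$enrichment)) tsv(res$enrichment, "enrichment.tsv")
  if (length(res$tipping_points) > 0)
    tsv(data.frame(pathway = names(res$tipping_points),
                   mean_vertex = vapply(res$tipping_points, `[[`, 0, "mean_vertex"),
                   sd_vertex = vapply(res$tipping_points, `[[`, 0, "sd_vertex"),
                   n_members = vapply(res$tipping_points, `[[`, 0L, "n_members")),
        "pathway_tipping_points.tsv")
  jsonlite::write_json(res$onset[c("b", "L", "x0", "k", "rss", "onset_age",
                                   "end_age", "fast_start", "fast_end",
                                   "epsilon")],
                       file.path(o, "onset.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tsv(res$timeline, "timeline.tsv")
  invisible(o)
}
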