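#' Generate a sorted vector of sample ages
#'
#' Ages are drawn uniformly over `[age_min, age_max]` and sorted ascending,
#' emulating a cross-sectional adult cohort in which age is treated as a
#' continuous covariate with no designed spacing.
#'
#' @param n Number of samples (>= 3).
#' @param age_min,age_max Age range in years; defaults span the adult baboon
#'   cohort the pipeline is designed around (7.5-22.1 years).
#' @param seed Integer seed; the call is reproducible for a fixed seed.
#' @return Numeric vector of `n` ages, sorted ascending.
#' @export
#' @examples
#' generate_ages(35, seed = 1)
generate_ages <- function(n, age_min = 7.5, age_max = 22.1, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    stop_invalid("n must be a single number >= 3")
  if (age_min >= age_max) stop_invalid("age_min must be < age_max")
  set.seed(split_seed(seed, "ages"))
  sort(runif(as.integer(n), age_min, age_max))
}

#' Describe one planted co-expression module
#'
#' @param module_id Positive integer label (0 is reserved for unassigned
#'   background transcripts).
#' @param n_transcripts Number of member transcripts; must reach the intended
#'   minimum module size for the module to be recoverable downstream.
#' @param trajectory One of `"flat"`, `"linear"`, `"quadratic"`: the shape of
#'   the shared latent log-expression signal as a function of age.
#' @param slope Linear slope (log-units per year); linear modules only.
#' @param vertex_age Vertex (tipping-point) age in years; quadratic only.
#' @param curvature Quadratic coefficient (log-units per year^2); its sign is
#'   the post-vertex direction of the module.
#' @param cor Target within-module Pearson correlation of member signals
#'   before count noise, in (0, 1].
#' @return A one-row data frame; rows are stacked into a module plan.
#' @export
module_spec <- function(module_id, n_transcripts, trajectory = c("flat", "linear", "quadratic"),
                        slope = 0, vertex_age = NA_real_, curvature = 0, cor = 0.8) {
  trajectory <- match.arg(trajectory)
  if (n_transcripts < 1) stop_invalid("module ", module_id, ": n_transcripts must be >= 1")
  if (trajectory == "quadratic" && !is.finite(vertex_age))
    stop_invalid("module ", module_id, ": quadratic modules need a vertex_age")
  if (trajectory != "quadratic") vertex_age <- NA_real_
  if (cor <= 0 || cor > 1) stop_invalid("within-module cor must be in (0, 1]")
  data.frame(module_id = as.integer(module_id), n_transcripts = as.integer(n_transcripts),
             trajectory = trajectory, slope = slope, vertex_age = vertex_age,
             curvature = curvature, cor = cor, stringsAsFactors = FALSE)
}

#' Default planted module plan
#'
#' Four recoverable modules of 40 transcripts emulating the archetypes seen in
#' aging heart transcriptomes - a metabolic module that declines after an early
#' tipping point, two anabolic/remodeling modules that rise after later tipping
#' points, and a linearly increasing module - plus 80 unassigned background
#' transcripts (module 0) with no shared signal.
#'
#' @param n_background Number of uncorrelated background transcripts.
#' @return Module-plan data frame (one row per module, see [module_spec()]).
#' @export
default_module_plan <- function(n_background = 80L) {
  rbind(
    module_spec(1L, 40L, "quadratic", vertex_age = 12.5, curvature = -0.050, cor = 0.95),
    module_spec(2L, 40L, "quadratic", vertex_age = 13.65, curvature = 0.050, cor = 0.95),
    module_spec(3L, 40L, "linear", slope = 0.08, cor = 0.95),
    module_spec(4L, 40L, "quadratic", vertex_age = 14.8, curvature = 0.050, cor = 0.95),
    data.frame(module_id = 0L, n_transcripts = as.integer(n_background),
               trajectory = "flat", slope = 0, vertex_age = NA_real_,
               curvature = 0, cor = 1, stringsAsFactors = FALSE)
  )
}

#' Assemble a ground-truth object for synthetic cohort generation
#'
#' Bundles everything the generators need: sample ages, the planted module
#' plan, a pathway plan (gene sets with planted member directions), staining
#' sigmoid parameters, and noise levels. All downstream randomness flows from
#' `seed` through named sub-streams, so outputs are reproducible and adding a
#' stage never perturbs another stage's draws.
#'
#' @param sample_ages Ages in years, one per sample.
#' @param module_plan Data frame from stacked [module_spec()] rows.
#' @param pathway_plan Optional list of pathways (see [default_pathway_plan()]);
#'   built from the module plan when `NULL`.
#' @param staining_params List with `baseline`, `amplitude`, `midpoint_age`,
#'   `rate` of the logistic staining-fraction curve. Defaults place the
#'   accumulation window (tangent method) at 11.3-21.3 years.
#' @param noise List with `dispersion` (negative-binomial dispersion; 0 gives
#'   Poisson counts), `shared_sd` (sd of the shared non-age module wiggle, in
#'   log-units) and `staining_sd` (Gaussian sd of staining fractions).
#' @param seed Master integer seed.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(sample_ages,
                         module_plan = default_module_plan(),
                         pathway_plan = NULL,
                         staining_params = list(baseline = 0.02, amplitude = 0.10,
                                                midpoint_age = 16.3, rate = 0.4),
                         noise = list(dispersion = 0.02, shared_sd = 0.6, staining_sd = 0.005),
                         seed = 1L) {
  if (length(sample_ages) < 3 || any(!is.finite(sample_ages)))
    stop_invalid("sample_ages must be >= 3 finite ages")
  if (any(module_plan$n_transcripts < 1)) stop_invalid("module plan has an empty module")
  quad <- module_plan$trajectory == "quadratic"
  if (any(quad & (module_plan$vertex_age < min(sample_ages) |
                  module_plan$vertex_age > max(sample_ages))))
    stop_invalid("all planted vertex ages must lie inside the sampled age range")
  truth <- structure(list(sample_ages = as.numeric(sample_ages),
                          module_plan = module_plan,
                          pathway_plan = pathway_plan,
                          staining_params = staining_params,
                          noise = noise, seed = as.integer(seed)),
                     class = "ground_truth")
  if (is.null(truth$pathway_plan))
    truth$pathway_plan <- default_pathway_plan(module_plan)
  truth
}

# Latent log-scale trajectory of a module at the given ages, centred so the
# transcript baseline carries the overall expression level.
module_trajectory <- function(row, ages) {
  switch(row$trajectory,
         flat = rep(0, length(ages)),
         linear = row$slope * (ages - mean(range(ages))),
         quadratic = row$curvature * ((ages - row$vertex_age)^2 -
                                        mean((ages - row$vertex_age)^2)))
}

# Planted direction of a module: post-vertex slope sign for quadratic
# trajectories, slope sign for linear, 0 for flat.
module_direction <- function(row) {
  switch(row$trajectory,
         flat = 0L,
         linear = as.integer(sign(row$slope)),
         quadratic = as.integer(sign(row$curvature)))
}

#' Default pathway plan derived from a module plan
#'
#' Builds one coherent gene set per non-background module (20 members, all
#' carrying the module's planted direction) and one null set of background
#' transcripts, mimicking curated pathway definitions with controlled up/down
#' composition.
#'
#' @param module_plan Module-plan data frame.
#' @param set_size Members per pathway (capped at the module size).
#' @return List of pathways, each `list(pathway_id, members, direction)`.
#' @export
default_pathway_plan <- function(module_plan, set_size = 20L) {
  ids <- transcript_ids(module_plan)
  plan <- list()
  nice <- c("metabolism_decline", "gag_precursor_synthesis", "linear_growth",
            "cardiac_hypertrophy", "pathway")
  for (i in seq_len(nrow(module_plan))) {
    row <- module_plan[i, ]
    if (row$module_id == 0L) next
    members <- ids[[as.character(row$module_id)]]
    members <- members[seq_len(min(set_size, length(members)))]
    nm <- if (row$module_id <= length(nice)) nice[row$module_id] else
      paste0("pathway_m", row$module_id)
    plan[[length(plan) + 1L]] <- list(
      pathway_id = nm, members = members,
      direction = rep(module_direction(row), length(members)))
  }
  if ("0" %in% names(ids)) {
    bg <- ids[["0"]]
    bg <- bg[seq_len(min(set_size, length(bg)))]
    plan[[length(plan) + 1L]] <- list(pathway_id = "null_background",
                                      members = bg,
                                      direction = rep(0L, length(bg)))
  }
  plan
}

# Deterministic transcript IDs per module: t<module>_<index> for members,
# bg_<index> for background.
transcript_ids <- function(module_plan) {
  out <- list()
  for (i in seq_len(nrow(module_plan))) {
    row <- module_plan[i, ]
    out[[as.character(row$module_id)]] <-
      if (row$module_id == 0L) sprintf("bg_%03d", seq_len(row$n_transcripts))
      else sprintf("t%d_%03d", row$module_id, seq_len(row$n_transcripts))
  }
  out
}

#' Generate a raw-count expression matrix with planted module structure
#'
#' Each module's members share a latent log-scale signal (its age trajectory
#' plus a shared Gaussian wiggle), scaled by per-transcript loadings in
#' `[0.6, 1]`, with member-specific Gaussian noise calibrated so members
#' correlate at the plan's declared level before count noise. Counts are drawn
#' negative-binomially with mean `exp(latent)` times a log-normal per-sample
#' library-size factor (Poisson when dispersion is 0).
#'
#' @param truth A [ground_truth()] object.
#' @return List with `counts` (integer matrix, transcripts x samples),
#'   `latent` (log-scale latent signals before count noise), `lib_factors`,
#'   and `truth_table` (per-transcript module, trajectory, vertex, loading).
#' @export
generate_expression <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  ages <- truth$sample_ages
  n <- length(ages)
  plan <- truth$module_plan
  if (any(plan$n_transcripts < 1)) stop_invalid("module plan has an empty module")
  ids <- transcript_ids(plan)

  set.seed(split_seed(truth$seed, "expression"))
  lib_factors <- rlnorm(n, meanlog = 0, sdlog = 0.15)

  rows <- list(); tt <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    m <- row$n_transcripts
    traj <- module_trajectory(row, ages)
    shared_wiggle <- if (row$module_id == 0L) rep(0, n)
      else rnorm(n, 0, truth$noise$shared_sd %||% 0)
    shared <- traj + shared_wiggle
    loading <- if (m == 1L) 1 else seq(0.6, 1.0, length.out = m)
    base <- runif(m, log(50), log(500))
    # Member-specific noise sd chosen so cor(member_j, member_k) = row$cor.
    v_shared <- var(shared) * (n - 1) / n
    tau <- if (row$cor >= 1 || v_shared == 0) 0 else
      sqrt(v_shared * (1 - row$cor) / row$cor)
    # Background transcripts carry independent profiles so they stay unclustered.
    if (row$module_id == 0L) tau <- truth$noise$shared_sd %||% 0.3
    lat <- matrix(0, m, n)
    for (j in seq_len(m))
      lat[j, ] <- base[j] + loading[j] * (shared + rnorm(n, 0, tau))
    rownames(lat) <- ids[[as.character(row$module_id)]]
    rows[[i]] <- lat
    tt[[i]] <- data.frame(transcript_id = rownames(lat),
                          module_id = row$module_id,
                          trajectory = row$trajectory,
                          vertex_age = row$vertex_age,
                          direction = module_direction(row),
                          loading = loading, stringsAsFactors = FALSE)
  }
  latent <- do.call(rbind, rows)
  truth_table <- do.call(rbind, tt)
  colnames(latent) <- sprintf("s%02d", seq_len(n))

  mu <- exp(latent) * rep(lib_factors, each = nrow(latent))
  disp <- truth$noise$dispersion %||% 0
  counts <- if (disp > 0)
    matrix(rnbinom(length(mu), mu = mu, size = 1 / disp), nrow(mu), ncol(mu))
  else
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
  dimnames(counts) <- dimnames(latent)
  list(counts = counts, latent = latent, lib_factors = lib_factors,
       truth_table = truth_table)
}

#' Generate synthetic staining-fraction measurements
#'
#' Per-animal expected fraction follows the planted logistic
#' `baseline + amplitude / (1 + exp(-rate * (age - midpoint)))`; each of
#' `images_per_animal` replicate images adds independent Gaussian noise
#' (clamped to `[0, 1]`), emulating replicate field-of-view quantification of
#' histological sections.
#'
#' @param truth A [ground_truth()] object.
#' @param n_animals Number of animals; defaults to all sampled ages.
#' @param images_per_animal Replicate images per animal (default 6).
#' @return Data frame with `animal`, `age`, `image_id`, `fraction`.
#' @export
generate_staining <- function(truth, n_animals = length(truth$sample_ages),
                              images_per_animal = 6L) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$staining_params
  if (p$amplitude <= 0 || p$rate <= 0)
    stop_invalid("staining amplitude and rate must be positive")
  if (p$baseline < 0 || p$baseline + p$amplitude > 1)
    stop_invalid("expected staining fractions must stay inside [0, 1]")
  ages <- truth$sample_ages[seq_len(min(n_animals, length(truth$sample_ages)))]
  expected <- p$baseline + p$amplitude / (1 + exp(-p$rate * (ages - p$midpoint_age)))
  set.seed(split_seed(truth$seed, "staining"))
  out <- expand.grid(image_id = seq_len(images_per_animal),
                     animal = seq_along(ages))
  out$age <- ages[out$animal]
  sdv <- truth$noise$staining_sd %||% 0
  out$fraction <- pmin(1, pmax(0, expected[out$animal] +
                                 if (sdv > 0) rnorm(nrow(out), 0, sdv) else 0))
  out[order(out$animal, out$image_id), c("animal", "age", "image_id", "fraction")]
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: generates ages, assembles the ground truth, and draws
#' expression counts and staining fractions in one call.
#'
#' @param n_samples Number of animals/samples.
#' @param seed Master seed.
#' @param age_min,age_max Age range in years.
#' @param module_plan,staining_params,noise Passed to [ground_truth()].
#' @return List with `truth`, `ages`, `expression` (see
#'   [generate_expression()]), `staining`, and `pathways` (named list of
#'   member IDs, GMT-ready).
#' @export
simulate_cohort <- function(n_samples = 35L, seed = 1L,
                            age_min = 7.5, age_max = 22.1,
                            module_plan = default_module_plan(),
                            staining_params = NULL, noise = NULL) {
  ages <- generate_ages(n_samples, age_min, age_max, seed = seed)
  args <- list(sample_ages = ages, module_plan = module_plan, seed = seed)
  if (!is.null(staining_params)) args$staining_params <- staining_params
  if (!is.null(noise)) args$noise <- noise
  truth <- do.call(ground_truth, args)
  expr <- generate_expression(truth)
  staining <- generate_staining(truth)
  pathways <- setNames(lapply(truth$pathway_plan, `[[`, "members"),
                       vapply(truth$pathway_plan, `[[`, "", "pathway_id"))
  list(truth = truth, ages = ages, expression = expr,
       staining = staining, pathways = pathways)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `counts.tsv` (transcript rows, sample columns), `ages.csv`
#' (`sample_id, age_years`), `pathways.gmt`, `staining.csv`, and a
#' `truth.json` sidecar holding the full ground truth.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- cohort$expression$counts
  paths <- c(counts = file.path(dir, "counts.tsv"),
             ages = file.path(dir, "ages.csv"),
             gmt = file.path(dir, "pathways.gmt"),
             staining = file.path(dir, "staining.csv"),
             truth = file.path(dir, "truth.json"))
  write.table(data.frame(transcript_id = rownames(counts), counts,
                         check.names = FALSE),
              paths[["counts"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(counts),
                         age_years = cohort$ages),
              paths[["ages"]], sep = ",", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$pathways, paths[["gmt"]])
  write.table(cohort$staining, paths[["staining"]], sep = ",", quote = FALSE,
              row.names = FALSE)
  truth <- cohort$truth
  truth$pathway_plan <- lapply(truth$pathway_plan, function(p)
    list(pathway_id = p$pathway_id, members = p$members, direction = p$direction))
  jsonlite::write_json(unclass(truth), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
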