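#' Configuration for a full pipeline run
#'
#' Bundles all stage options: task statistics, cohort composition and group
#' effects, regression options, inference options, and whether to run the
#' (comparatively expensive) per-subject model fits. A single global seed is
#' fanned out to per-stage streams (cohort, task sessions, agent noise,
#' fitting, permutations) by drawing stage seeds from the global stream, so
#' each stage is independently reproducible.
#'
#' @param n_young,n_old Subjects per group.
#' @param task A [task_config()].
#' @param effects A [cohort_effects()].
#' @param model A [model_config()] used for the conditioned regressors.
#' @param fit_models Run MAP fits per subject?
#' @param fit_restarts Optimizer restarts per fit.
#' @param lambda Ridge parameter for the windowed regression.
#' @param n_bins Number of sliding bins.
#' @param window_frac Fraction of trials per bin.
#' @param n_perm Permutations for the cluster tests.
#' @param smooth_width Bin smoothing width for the cluster tests.
#' @param cluster_terms Coefficients to submit to the cluster tests.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_young = 10, n_old = 10, task = task_config(),
                            effects = cohort_effects(),
                            model = model_config(),
                            fit_models = FALSE, fit_restarts = 3,
                            lambda = 0.1, n_bins = 90, window_frac = 0.1,
                            n_perm = 1000, smooth_width = 5,
                            cluster_terms = c("delta", "delta_x_surprise",
                                              "delta_x_uncertainty"),
                            seed = 1L) {
  stopifnot(inherits(task, "task_config"), inherits(effects, "cohort_effects"),
            inherits(model, "model_config"))
  if (is.null(seed)) stop("a global seed is required", call. = FALSE)
  structure(list(n_young = n_young, n_old = n_old, task = task,
                 effects = effects, model = model, fit_models = fit_models,
                 fit_restarts = fit_restarts, lambda = lambda,
                 n_bins = n_bins, window_frac = window_frac, n_perm = n_perm,
                 smooth_width = smooth_width, cluster_terms = cluster_terms,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> model -> (fit) -> regress -> infer. Generates a cohort of
#' agents, simulates each subject's task session and behaviour, assembles
#' regression datasets with model-derived regressors, estimates
#' heteroscedasticity weights from pooled initialization residuals, fits the
#' sliding-window penalized weighted regression per subject, runs
#' cluster-mass permutation tests (each group against zero and young vs
#' old) for the requested coefficients, extracts LOSO coefficients for the
#' uncertainty interaction and fits the age explanatory models. Re-running
#' with the same configuration reproduces every output exactly.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, all intermediate artifacts
#'   (cohort table, per-subject task/behaviour/coefficient tables, cluster
#'   test summaries, manifest) are written as CSV/JSON.
#' @return A list of class `pipeline_result` with `cohort`, `datasets`,
#'   `window_fits`, `fits` (if requested), `cluster_tests`, `loso`,
#'   `age_models`, and `manifest` (config hash, stage seeds, timings).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(label, t0) {
    timings[[label]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 5)
  names(stage_seeds) <- c("cohort", "sessions", "agents", "fitting",
                          "permutations")

  # --- cohort -------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  cohort <- generate_cohort(cfg$n_young, cfg$n_old, cfg$effects,
                            seed = stage_seeds[["cohort"]])
  n <- nrow(cohort$subjects)
  set.seed(stage_seeds[["sessions"]])
  session_seeds <- sample.int(.Machine$integer.max - 1L, n)
  tick("cohort", t0)

  # --- simulate sessions and behaviour ------------------------------------
  t0 <- proc.time()[["elapsed"]]
  sessions <- vector("list", n)
  behaviours <- vector("list", n)
  for (i in seq_len(n)) {
    sessions[[i]] <- generate_task_session(cfg$task,
                                           seed = session_seeds[i],
                                           counterbalance = TRUE)
    behaviours[[i]] <- simulate_agent(sessions[[i]], cohort$agents[[i]],
                                      cfg = cfg$model)
  }
  tick("simulate", t0)

  # --- datasets, weights, windowed regression -----------------------------
  t0 <- proc.time()[["elapsed"]]
  datasets <- vector("list", n)
  for (i in seq_len(n))
    datasets[[i]] <- make_regression_dataset(sessions[[i]], behaviours[[i]],
                                             cfg$model)
  weights <- estimate_heteroscedastic_weights(datasets,
                                              window_frac = cfg$window_frac)
  window_fits <- vector("list", n)
  for (i in seq_len(n))
    window_fits[[i]] <- sliding_window_fit(datasets[[i]], weights[[i]],
                                           lambda = cfg$lambda,
                                           n_bins = cfg$n_bins,
                                           window_frac = cfg$window_frac)
  tick("regress", t0)

  # --- optional model fitting ---------------------------------------------
  fits <- NULL
  if (cfg$fit_models) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(stage_seeds[["fitting"]])
    fit_seeds <- sample.int(.Machine$integer.max - 1L, n)
    fits <- vector("list", n)
    for (i in seq_len(n)) {
      sd_i <- subject_data(sessions[[i]], behaviours[[i]])
      fits[[i]] <- fit_subject(sd_i, n_restarts = cfg$fit_restarts,
                               seed = fit_seeds[i])
    }
    tick("fit", t0)
  }

  # --- group inference -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  young <- cohort$subjects$group == "young"
  set.seed(stage_seeds[["permutations"]])
  perm_seeds <- sample.int(.Machine$integer.max - 1L,
                           3 * length(cfg$cluster_terms))
  cluster_tests <- list()
  k <- 0L
  for (term in cfg$cluster_terms) {
    cm <- coef_matrix(window_fits, term)
    cluster_tests[[term]] <- list(
      young = cluster_mass_permutation_test(
        cm[young, , drop = FALSE], n_perm = cfg$n_perm,
        smooth_width = cfg$smooth_width, seed = perm_seeds[k + 1L]),
      old = cluster_mass_permutation_test(
        cm[!young, , drop = FALSE], n_perm = cfg$n_perm,
        smooth_width = cfg$smooth_width, seed = perm_seeds[k + 2L]),
      group = cluster_mass_permutation_test(
        cm[young, , drop = FALSE], cm[!young, , drop = FALSE],
        n_perm = cfg$n_perm, smooth_width = cfg$smooth_width,
        seed = perm_seeds[k + 3L]))
    k <- k + 3L
  }

  unc <- coef_matrix(window_fits, "delta_x_uncertainty")
  unc_s <- smooth_across_bins(unc, cfg$smooth_width)
  loso <- loso_extract(unc_s[young, , drop = FALSE],
                       unc_s[!young, , drop = FALSE])
  loso_aligned <- numeric(n)
  loso_aligned[young] <- loso$value[loso$group == "a"]
  loso_aligned[!young] <- loso$value[loso$group == "b"]
  age_models <- list(
    loso_uncertainty = age_explanatory_model(cohort$subjects, loso_aligned))
  if (!is.null(fits)) {
    fitted_log_uu <- vapply(fits, function(f)
      if (is.null(f$params)) NA_real_ else f$params$log_uu, numeric(1))
    age_models$log_uu <- age_explanatory_model(cohort$subjects, fitted_log_uu)
  }
  tick("infer", t0)

  cfg_json <- as.character(jsonlite::toJSON(
    .config_fields(cfg), auto_unbox = TRUE, digits = NA))
  manifest <- list(
    schema = .SCHEMA_VERSION,
    config = .config_fields(cfg),
    config_hash = .content_hash(cfg_json),
    stage_seeds = as.list(stage_seeds),
    n_subjects = n,
    timings_s = as.list(timings),
    total_s = round(proc.time()[["elapsed"]] - t_start, 3))

  result <- structure(
    list(cohort = cohort, sessions = sessions, behaviours = behaviours,
         datasets = datasets, window_fits = window_fits, fits = fits,
         cluster_tests = cluster_tests, loso = loso,
         age_models = age_models, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_artifacts(result, out_dir)
  result
}

.config_fields <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x)
}

.write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(result$cohort$subjects, file.path(out_dir, "cohort.csv"))
  n <- length(result$sessions)
  for (i in seq_len(n)) {
    write_table_csv(result$sessions[[i]],
                    file.path(out_dir, sprintf("task_%02d.csv", i)))
    write_table_csv(result$behaviours[[i]],
                    file.path(out_dir, sprintf("behavior_%02d.csv", i)))
    wf <- result$window_fits[[i]]
    wf$subject <- i
    write_table_csv(wf, file.path(out_dir, sprintf("coefficients_%02d.csv", i)))
  }
  cl <- lapply(result$cluster_tests, function(term) {
    lapply(term, function(ct) list(
      test = ct$test, n_perm = ct$n_perm, smooth_width = ct$smooth_width,
      clusters = ct$clusters))
  })
  writeLines(jsonlite::toJSON(cl, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", pretty = TRUE),
             file.path(out_dir, "cluster_tests.json"))
  write_table_csv(result$loso, file.path(out_dir, "loso.csv"))
  if (!is.null(result$fits))
    for (i in seq_along(result$fits))
      fit_to_json(result$fits[[i]],
                  file.path(out_dir, sprintf("fit_%02d.json", i)))
  writeLines(jsonlite::toJSON(result$manifest, auto_unbox = TRUE,
                              digits = NA, null = "null", na = "null",
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d subjects, %d coefficient cluster tests, %s\n",
              x$manifest$n_subjects, length(x$cluster_tests),
              if (is.null(x$fits)) "no model fits" else "with model fits"))
  cat(sprintf("  config hash %s, total %.1f s\n", x$manifest$config_hash,
              x$manifest$total_s))
  invisible(x)
}

#' Generate the miniature fixture cohort
#'
#' Writes a deterministic six-subject cohort (one agent of each model kind
#' plus one extra normative agent) performing two 100-trial blocks, as plain
#' CSV files (`task_*.csv`, `behavior_*.csv`, `cohort.csv`) plus a JSON
#' manifest. Regeneration with the same seed is byte-identical, which makes
#' the fixtures suitable for fast regression tests.
#'
#' @param dir Output directory.
#' @param seed Integer seed (the packaged default defines the canonical
#'   fixture set).
#' @return The directory, invisibly.
#' @export
make_fixtures <- function(dir, seed = 20160601) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- task_config(n_trials = 100L)
  kinds <- c("normative", "surprise_insensitive", "low_hazard",
             "uncertainty_underestimation", "fixed_learning_rate",
             "normative")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * length(kinds))
  rows <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    agent <- agent_spec(kinds[i], update_variability = 3,
                        lr_variability = 0.1, seed = seeds[2 * i])
    session <- generate_task_session(cfg, seed = seeds[2 * i - 1])
    beh <- simulate_agent(session, agent)
    write_table_csv(session, file.path(dir, sprintf("task_%02d.csv", i)))
    write_table_csv(beh, file.path(dir, sprintf("behavior_%02d.csv", i)))
    rows[[i]] <- data.frame(subject = i, model_kind = kinds[i],
                            task_seed = seeds[2 * i - 1],
                            agent_seed = seeds[2 * i])
  }
  write_table_csv(do.call(rbind, rows), file.path(dir, "cohort.csv"))
  writeLines(jsonlite::toJSON(
    list(schema = .SCHEMA_VERSION, seed = seed, n_subjects = length(kinds),
         n_trials_per_block = cfg$n_trials, noise_sds = cfg$noise_sds),
    auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(dir, "fixtures.json"))
  invisible(dir)
}
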