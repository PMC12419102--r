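#' Run the full virtual-twin benchmarking pipeline
#'
#' End-to-end driver: screen features, fit the pooled overall risk model
#' and one risk model per hospital, fit per-hospital anomaly scorers,
#' estimate every patient's causal relative risk against the overall
#' hospital for every focal hospital, screen bad virtual twins, grade
#' hospitals with standardized-beta panels, and (optionally) write all
#' tables, figures and a run manifest to an output directory.
#'
#' @param cohort Cohort tibble with id, group, outcome and covariate
#'   columns (e.g. from [simulate_cohort()] or [read_cohort()]).
#' @param outcome,group_col,id_col Column names.
#' @param features Feature list; `NULL` (default) runs
#'   [screen_features()].
#' @param top_k Features kept by the screen.
#' @param threshold Anomaly-score cutoff `C` (default 0.05). `C = 0`
#'   disables the filter (all rows kept).
#' @param variables Covariates for the per-variable beta panels; default
#'   the first three screened features.
#' @param num_trees,min_node_size,node_fraction Risk-forest settings
#'   (see [fit_risk_model()]; `min_node_size = NULL` scales terminal
#'   nodes to `node_fraction` of each model's training size).
#' @param iforest_trees,iforest_sample Isolation-forest settings.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional output directory; when given, writes
#'   `estimates.csv`, `beta_table.csv`, `summary.json`, `manifest.json`
#'   and SVG figures with their numeric plot data as CSV.
#' @return A list of class `vt_run`: `estimates` (all focal hospitals
#'   row-bound), `betas`, `models`, `scorers`, `features`, `manifest`.
#' @export
run_pipeline <- function(cohort, outcome = "y", group_col = "hospital",
                         id_col = "id", features = NULL, top_k = 10,
                         threshold = 0.05, variables = NULL,
                         num_trees = 500, min_node_size = NULL,
                         node_fraction = 0.05,
                         iforest_trees = 300, iforest_sample = 256,
                         seed = 1, out_dir = NULL) {
  check_cols(cohort, c(outcome, group_col, id_col))
  check_binary_outcome(cohort[[outcome]], outcome)
  hospitals <- levels(factor(cohort[[group_col]]))
  log_stage <- function(fmt, ...) message(sprintf(paste0("[vtwins] ", fmt), ...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed (%d rows processed): %s",
                    name, nrow(cohort), conditionMessage(e)))
    })
  }

  log_stage("screening features")
  features <- stage("screen", screen_features(
    cohort, outcome = outcome, group_col = group_col, id_col = id_col,
    supplied = features, top_k = top_k, seed = child_seed(seed, 1)))
  if (is.null(variables)) variables <- utils::head(features, 3)

  log_stage("fitting overall risk model (n = %d)", nrow(cohort))
  model_o <- stage("fit_overall", fit_risk_model(
    cohort, scope = "overall", outcome = outcome, group_col = group_col,
    id_col = id_col, features = features, num_trees = num_trees,
    min_node_size = min_node_size, node_fraction = node_fraction,
    seed = child_seed(seed, 2)))

  oob_o <- predict_risk_oob(model_o)   # shared denominator, computed once
  models <- list()
  scorers <- list()
  estimates <- list()
  for (i in seq_along(hospitals)) {
    h <- hospitals[i]
    log_stage("hospital %s: risk model, scorer, causal estimates", h)
    models[[h]] <- stage(paste0("fit_", h), fit_risk_model(
      cohort, scope = h, outcome = outcome, group_col = group_col,
      id_col = id_col, features = features, num_trees = num_trees,
      min_node_size = min_node_size, node_fraction = node_fraction,
      seed = child_seed(seed, 100 + i)))
    scorers[[h]] <- stage(paste0("scorer_", h), fit_anomaly_scorer(
      cohort, group = h, features = features, group_col = group_col,
      id_col = id_col, num_trees = iforest_trees,
      sample_size = iforest_sample, seed = child_seed(seed, 200 + i)))
    est <- stage(paste0("effects_", h), {
      if (threshold > 0) {
        estimate_effects(cohort, h, models[[h]], model_o, scorers[[h]],
                         threshold = threshold, group_col = group_col,
                         id_col = id_col, oob_overall = oob_o)
      } else {
        e <- estimate_effects(cohort, h, models[[h]], model_o, scorers[[h]],
                              threshold = 1e-12, group_col = group_col,
                              id_col = id_col, oob_overall = oob_o)
        e$keep <- TRUE
        e
      }
    })
    estimates[[h]] <- est
  }
  all_est <- dplyr::bind_rows(estimates)
  class(all_est) <- c("vt_estimates", class(tibble::tibble()))
  attr(all_est, "threshold") <- threshold

  log_stage("standardized-beta grading")
  betas <- stage("betas", beta_table(all_est, cohort = cohort,
                                     variables = variables, id_col = id_col))

  kept_counts <- all_est |>
    dplyr::group_by(.data$focal) |>
    dplyr::summarise(n = dplyr::n(), kept = sum(.data$keep),
                     .groups = "drop")
  manifest <- list(
    config = list(outcome = outcome, group_col = group_col,
                  threshold = threshold, num_trees = num_trees,
                  min_node_size = min_node_size,
                  iforest_trees = iforest_trees,
                  iforest_sample = iforest_sample, seed = seed,
                  features = features, variables = variables),
    config_hash = rlang::hash(list(outcome, group_col, threshold,
                                   num_trees, min_node_size, iforest_trees,
                                   iforest_sample, seed, features, variables)),
    versions = list(vtwins = as.character(utils::packageVersion("vtwins")),
                    ranger = as.character(utils::packageVersion("ranger")),
                    r = R.version.string),
    n = nrow(cohort),
    hospitals = hospitals,
    kept_counts = stats::setNames(as.list(kept_counts$kept),
                                  kept_counts$focal)
  )

  run <- structure(
    list(estimates = all_est, betas = betas, models = models,
         scorers = scorers, model_overall = model_o, features = features,
         manifest = manifest),
    class = "vt_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.vt_run <- function(x, ...) {
  cat("<vt_run>\n")
  cat(sprintf("  hospitals: %s\n", paste(x$manifest$hospitals, collapse = ", ")))
  cat(sprintf("  patients: %d  features: %d  threshold C: %.3f\n",
              x$manifest$n, length(x$features),
              x$manifest$config$threshold))
  kc <- unlist(x$manifest$kept_counts)
  cat(sprintf("  kept estimates per hospital: %s\n",
              paste(sprintf("%s=%d", names(kc), kc), collapse = ", ")))
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Emits the per-patient estimates and beta table as CSV, a per-hospital
#' summary and the run manifest as JSON, and the diagnostic figures as
#' SVG alongside their numeric plot data as CSV (so every graphic can be
#' regenerated from text).
#'
#' @param run A `vt_run` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "vt_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(run$estimates),
                   file.path(dir, "estimates.csv"))
  readr::write_csv(tibble::as_tibble(run$betas),
                   file.path(dir, "beta_table.csv"))

  summary_tbl <- run$estimates |>
    dplyr::filter(.data$keep) |>
    dplyr::group_by(.data$focal, .data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$tau, 0.25, names = FALSE),
      median = stats::median(.data$tau),
      q3 = stats::quantile(.data$tau, 0.75, names = FALSE),
      .groups = "drop"
    )
  jsonlite::write_json(summary_tbl, file.path(dir, "summary.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  save_fig <- function(stem, plot, width, height) {
    ggplot2::ggsave(file.path(dir, paste0(stem, ".svg")), plot,
                    width = width, height = height,
                    device = grDevices::svg)
    ggplot2::ggsave(file.path(dir, paste0(stem, ".png")), plot,
                    width = width, height = height, dpi = 150,
                    device = grDevices::png)
  }
  p_eff <- plot_hospital_effects(run$estimates)
  save_fig("hospital_effects", p_eff, 10, 4)
  readr::write_csv(attr(p_eff, "plot_data"),
                   file.path(dir, "hospital_effects_data.csv"))
  p_den <- plot_anomaly_density(run$estimates,
                                threshold = run$manifest$config$threshold)
  save_fig("anomaly_density", p_den, 8, 6)
  readr::write_csv(
    tibble::as_tibble(run$estimates)[, c("focal", "anomaly_score")],
    file.path(dir, "anomaly_scores.csv"))
  p_beta <- plot_beta_grades(run$betas)
  save_fig("beta_grades", p_beta, 10, 8)
  invisible(dir)
}
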