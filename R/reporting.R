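#' Run the full analysis pipeline
#'
#' Chains every stage: assign work weeks, build the weekly reconciled
#' networks, extract the 26-feature person-week matrix, compute the RMSSD
#' outcome table, fit the five trait-specific LOSO boosted-tree models,
#' and derive the scaled cross-trait importance profile. Normalized RMSE
#' uses the pooled observed RMSSD range across all five traits.
#'
#' @param interactions Parsed interaction records
#'   ([parse_interaction_log()]).
#' @param ema Parsed EMA records ([parse_ema_log()]).
#' @param weeks Work-week calendar ([work_weeks()]).
#' @param grid Hyperparameter grid for the boosted trees.
#' @param seed Base seed for tuning, fitting and permutation importance.
#' @param importance_source `"pooled"` (default: one tuned model per trait
#'   on the full table) or `"folds"` (per-fold importance averaged across
#'   LOSO folds; considerably slower).
#' @param n_repeats Permutation repeats per feature.
#' @param comparators Also fit the penalized-linear and k-nearest-neighbour
#'   baselines.
#' @return List of class `egostates_run`: `networks`, `features`,
#'   `outcomes`, `outcome_summary`, per-trait `models` (each a
#'   `loso_result`), `participant_summary`, `importance` (aggregated
#'   table), `scaled_importance` (per-trait list), `comparators` (or
#'   `NULL`), `norm_range`.
#' @export
run_pipeline <- function(interactions, ema, weeks,
                         grid = default_grid(reduced = TRUE), seed = 2012,
                         importance_source = c("pooled", "folds"),
                         n_repeats = 10, comparators = FALSE) {
  importance_source <- match.arg(importance_source)
  interactions <- split_work_weeks(interactions, weeks)
  ema <- split_work_weeks(ema, weeks)
  networks <- build_weekly_networks(interactions, weeks)
  features <- assemble_feature_matrix(networks, seed = seed)
  outcomes <- build_outcome_table(ema)
  outcome_summary <- summarize_outcomes(outcomes)
  norm_range <- diff(range(as.matrix(outcomes[TRAITS]), na.rm = TRUE))

  models <- list()
  scaled <- list()
  comp <- if (comparators) list() else NULL
  for (tr in TRAITS) {
    tab <- join_model_data(features, outcomes, tr)
    res <- run_loso(tab, grid = grid, seed = seed, norm_range = norm_range,
                    importance = importance_source == "folds",
                    n_repeats = n_repeats)
    models[[tr]] <- res
    scaled[[tr]] <- if (importance_source == "folds") {
      importance_profile(tab, loso = res, source = "folds")
    } else {
      importance_profile(tab, source = "pooled", grid = grid, seed = seed,
                         n_repeats = n_repeats)
    }
    if (comparators) {
      comp[[tr]] <- fit_comparators(tab, seed = seed, norm_range = norm_range)
    }
  }
  structure(list(
    networks = networks, features = features, outcomes = outcomes,
    outcome_summary = outcome_summary, models = models,
    participant_summary = summarize_participants(models),
    importance = aggregate_importance(scaled),
    scaled_importance = scaled, comparators = comp, norm_range = norm_range
  ), class = "egostates_run")
}

#' @export
print.egostates_run <- function(x, ...) {
  cat("egostates pipeline run\n")
  cat("  person-week feature rows :", nrow(x$features), "\n")
  cat("  outcome rows             :", nrow(x$outcomes), "\n")
  mr <- vapply(x$models, function(m) m$mean_r2, numeric(1))
  pr <- vapply(x$models, function(m) m$pooled_r2, numeric(1))
  cat("  mean fold R2 by trait    :",
      paste(sprintf("%s=%.2f", names(mr), mr), collapse = " "), "\n")
  cat("  pooled R2 by trait       :",
      paste(sprintf("%s=%.2f", names(pr), pr), collapse = " "), "\n")
  cat("  top features             :",
      paste(head(x$importance$feature, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Render the three report tables
#'
#' Writes the weekly outcome summary (median \[min, max\] RMSSD per week
#' and trait), the per-participant performance table (min/max/avg
#' R-squared and normalized RMSE with the consistently-informative flag,
#' sorted by minimum R-squared descending then average normalized RMSE
#' ascending) and the aggregated importance profile (sorted by descending
#' cross-trait average) as CSV files. Every cell is recomputed from the
#' pipeline artifacts; nothing is computed independently here.
#'
#' @param run An `egostates_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
render_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    outcome_summary = file.path(dir, "weekly_outcome_summary.csv"),
    participant_performance = file.path(dir, "participant_performance.csv"),
    feature_importance = file.path(dir, "feature_importance.csv")
  )
  write_table_csv(run$outcome_summary, paths["outcome_summary"])
  write_table_csv(run$participant_summary, paths["participant_performance"])
  write_table_csv(run$importance, paths["feature_importance"])
  invisible(paths)
}
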