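#' Permutation feature importance
#'
#' Model-agnostic importance by error inflation: for each predictor column,
#' its values are shuffled `n_repeats` times and the importance is the mean
#' increase in RMSE over the unshuffled baseline. Features the model never
#' uses change nothing and score ~0; negative means (permutation noise) are
#' floored at 0. The permutation RNG is seeded per feature so results are
#' reproducible and independent of column evaluation order.
#'
#' @param model Fitted model accepted by [stats::predict()] on a matrix
#'   (e.g. an `xgb.Booster`).
#' @param x Numeric predictor matrix (named columns).
#' @param y Observed outcomes.
#' @param n_repeats Shuffles per feature.
#' @param seed Integer seed.
#' @return Named numeric vector of raw importances (RMSE increase), one per
#'   column of `x`.
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10, seed = 2012) {
  stopifnot(nrow(x) == length(y), !is.null(colnames(x)))
  baseline <- sqrt(mean((predict(model, x) - y)^2))
  imp <- vapply(seq_len(ncol(x)), function(j) {
    if (length(unique(x[, j])) == 1) return(0) # constant feature
    deltas <- local_seed(seed + j, vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample(nrow(xp)), j]
      sqrt(mean((predict(model, xp) - y)^2)) - baseline
    }, numeric(1)))
    mean(deltas)
  }, numeric(1))
  names(imp) <- colnames(x)
  pmax(imp, 0)
}

#' Scale raw importances to 0--100
#'
#' Linear rescale so the largest raw importance maps to 100 and the
#' smallest to 0; an all-equal vector (including a single feature) maps to
#' all zeros. Invariant to affine transforms of the raw values.
#'
#' @param raw Named numeric vector of raw importances.
#' @return Named numeric vector on the 0--100 scale.
#' @export
scale_importances <- function(raw) {
  rng <- range(raw)
  if (diff(rng) == 0) return(stats::setNames(rep(0, length(raw)), names(raw)))
  100 * (raw - rng[1]) / diff(rng)
}

#' Aggregate scaled importances across the five trait models
#'
#' Row-wise mean of the five per-trait 0--100 scaled importance vectors,
#' sorted by descending average (ties broken alphabetically by feature
#' name).
#'
#' @param scaled Named list of five named numeric vectors (same feature
#'   set), names = traits.
#' @return Data.frame: `feature`, one column per trait, `average`, `rank`.
#' @export
aggregate_importance <- function(scaled) {
  feats <- names(scaled[[1]])
  for (s in scaled) {
    if (!setequal(names(s), feats)) {
      stop("importance vectors cover different feature sets")
    }
  }
  mat <- vapply(scaled, function(s) s[feats], numeric(length(feats)))
  out <- data.frame(feature = feats, mat, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out$average <- rowMeans(mat)
  out <- out[order(-out$average, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-trait importance profile from a LOSO run
#'
#' Convenience wrapper producing the scaled profile for one trait, either
#' from the fold-averaged raw importances already stored in a
#' [run_loso()] result, or (`source = "pooled"`) from a single tuned model
#' refit on the full modelling table — much cheaper when many profiles are
#' needed.
#'
#' @param table Modelling table for the trait.
#' @param loso Optional `loso_result` with `importance` filled in.
#' @param source `"folds"` (use `loso$importance`) or `"pooled"`.
#' @param grid,seed,n_repeats Used for the pooled refit.
#' @return Named numeric vector of 0--100 scaled importances for the 27
#'   predictors.
#' @export
importance_profile <- function(table, loso = NULL,
                               source = c("folds", "pooled"),
                               grid = default_grid(reduced = TRUE),
                               seed = 2012, n_repeats = 10) {
  source <- match.arg(source)
  if (source == "folds") {
    if (is.null(loso) || is.null(loso$importance)) {
      stop("source = 'folds' needs a run_loso() result with importance = TRUE")
    }
    return(scale_importances(loso$importance))
  }
  x <- as.matrix(table[predictor_columns()])
  fit <- tune_and_fit(x, table$outcome, table$participant_id, grid,
                      seed = seed)
  raw <- permutation_importance(fit$model, x, table$outcome,
                                n_repeats = n_repeats, seed = seed)
  scale_importances(raw)
}
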