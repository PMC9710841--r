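#' Canonical feature and predictor column names
#'
#' `feature_columns()` returns the 26 network feature names in canonical
#' order (9 global structural, 4 global nodal, 13 egocentric);
#' `predictor_columns()` appends the week index — the 27 predictors every
#' trait model is trained on.
#'
#' @return Character vector of length 26 / 27.
#' @export
feature_columns <- function() FEATURE_COLUMNS

#' @rdname feature_columns
#' @export
predictor_columns <- function() c(FEATURE_COLUMNS, "week")

#' Join features and outcomes into a modelling table
#'
#' Inner join of the person-week feature matrix and the outcome table on
#' (participant, week), keeping one outcome column. Person-weeks lacking
#' either side, or with an undefined outcome, are dropped with a logged
#' count.
#'
#' @param features Table from [assemble_feature_matrix()].
#' @param outcomes Table from [build_outcome_table()].
#' @param trait One of `"extra"`, `"agree"`, `"consc"`, `"stabl"`, `"open"`.
#' @return Data.frame with `participant_id`, `week`, the 27 predictors and
#'   an `outcome` column.
#' @export
join_model_data <- function(features, outcomes, trait = TRAITS) {
  trait <- match.arg(trait)
  out_small <- outcomes[c("participant_id", "week", trait)]
  names(out_small)[3] <- "outcome"
  joined <- merge(features, out_small, by = c("participant_id", "week"))
  before <- nrow(joined)
  joined <- joined[!is.na(joined$outcome), , drop = FALSE]
  ok <- complete.cases(joined[predictor_columns()])
  joined <- joined[ok, , drop = FALSE]
  if (nrow(joined) == 0) {
    stop("feature and outcome tables share no usable (participant, week) rows")
  }
  n_drop <- max(nrow(features), nrow(out_small)) - nrow(joined)
  message("modelling table for '", trait, "': ", nrow(joined), " rows (",
          before - nrow(joined), " joined rows dropped for missingness, ",
          n_drop, " unmatched)")
  joined <- joined[order(joined$participant_id, joined$week), , drop = FALSE]
  rownames(joined) <- NULL
  joined
}

#' Leave-one-subject-out folds
#'
#' One fold per participant: the fold's test side is all of that
#' participant's rows, its training side everything else.
#'
#' @param table Modelling table with a `participant_id` column.
#' @return Named list mapping participant id to integer test-row indices.
#' @export
loso_folds <- function(table) {
  ids <- sort(unique(table$participant_id))
  if (length(ids) < 2) stop("LOSO needs at least 2 participants")
  stats::setNames(lapply(ids, function(id) {
    which(table$participant_id == id)
  }), ids)
}

#' Hyperparameter grids for the boosted-tree learner
#'
#' The default grid crosses small candidate sets for the seven tunable
#' boosted-tree hyperparameters (boosting rounds, row subsample, feature
#' subsample, tree depth, minimum child weight, gamma, learning rate),
#' three levels per tunable where that is meaningful. `reduced = TRUE`
#' gives a 4-point grid (rounds x depth) for simulation studies where
#' thousands of fits are needed.
#'
#' @param reduced Use the small simulation grid.
#' @return Data.frame, one row per hyperparameter combination.
#' @export
default_grid <- function(reduced = FALSE) {
  if (reduced) {
    expand.grid(nrounds = c(50, 100), max_depth = c(2, 3), eta = 0.3,
                gamma = 0, colsample_bytree = 0.8, min_child_weight = 1,
                subsample = 0.75)
  } else {
    expand.grid(nrounds = c(50, 100, 150), max_depth = c(1, 2, 3),
                eta = c(0.3, 0.4), gamma = 0, colsample_bytree = c(0.6, 0.8),
                min_child_weight = 1, subsample = c(0.5, 0.75, 1))
  }
}

#' Tune and fit one boosted-tree regression
#'
#' Grid search by inner participant-grouped k-fold cross-validation:
#' training participants (not rows) are partitioned into `inner_k` folds so
#' no individual contributes to both sides of an inner split, each grid row
#' is scored by pooled inner RMSE, and the winner (ties: first row of the
#' grid) is refit on all training rows. Deterministic for a fixed seed; the
#' caller's RNG stream is untouched.
#'
#' @param x Numeric predictor matrix.
#' @param y Numeric outcome vector.
#' @param groups Participant id per row (inner grouping).
#' @param grid Hyperparameter grid from [default_grid()].
#' @param seed Integer seed.
#' @param inner_k Inner fold count (default 5, capped at the number of
#'   training participants).
#' @return List with `model` (an `xgb.Booster`), `params` (winning grid
#'   row), `inner_rmse` (per grid row), and `seed`.
#' @export
tune_and_fit <- function(x, y, groups, grid, seed = 2012, inner_k = 5) {
  stopifnot(nrow(x) == length(y), nrow(grid) >= 1)
  if (sd(y) == 0) {
    message("constant outcome in training data; fit is degenerate")
  }
  inner_rmse <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    ids <- sort(unique(groups))
    k <- min(inner_k, length(ids))
    fold_of <- local_seed(seed, sample(rep(seq_len(k), length.out = length(ids))))
    names(fold_of) <- ids
    for (gi in seq_len(nrow(grid))) {
      sq_err <- 0
      n_err <- 0
      for (f in seq_len(k)) {
        hold <- groups %in% ids[fold_of == f]
        m <- fit_xgb(x[!hold, , drop = FALSE], y[!hold], grid[gi, ], seed)
        pred <- predict(m, x[hold, , drop = FALSE])
        sq_err <- sq_err + sum((pred - y[hold])^2)
        n_err <- n_err + sum(hold)
      }
      inner_rmse[gi] <- sqrt(sq_err / n_err)
    }
    best <- which.min(inner_rmse)
  } else {
    best <- 1L
  }
  model <- fit_xgb(x, y, grid[best, ], seed)
  list(model = model, params = grid[best, , drop = FALSE],
       inner_rmse = inner_rmse, seed = seed)
}

#' Evaluate predictions on a held-out fold
#'
#' R-squared is the squared Pearson correlation between observed and
#' predicted values (the convention of the tooling this pipeline mirrors),
#' undefined — `NA` — with fewer than 3 test rows or zero variance on
#' either side; `r2_method = "ss"` switches to
#' \eqn{1 - SS_{res}/SS_{tot}} clamped to \[0, 1\]. The normalized RMSE
#' divides by `norm_range`, the observed span of the outcome.
#'
#' @param observed,predicted Numeric vectors.
#' @param norm_range Outcome range used for RMSE normalization.
#' @param r2_method `"cor"` (default) or `"ss"`.
#' @return Named list `r2`, `rmse`, `rmse_normalized`, `n`.
#' @export
evaluate_fold <- function(observed, predicted, norm_range,
                          r2_method = c("cor", "ss")) {
  r2_method <- match.arg(r2_method)
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  rmse <- sqrt(mean((observed - predicted)^2))
  n <- length(observed)
  r2 <- NA_real_
  if (r2_method == "cor") {
    if (n >= 3 && sd(observed) > 0 && sd(predicted) > 0) {
      r2 <- cor(observed, predicted)^2
    }
  } else {
    if (n >= 3 && sd(observed) > 0) {
      r2 <- max(0, min(1, 1 - sum((observed - predicted)^2) /
                         sum((observed - mean(observed))^2)))
    }
  }
  list(r2 = r2, rmse = rmse,
       rmse_normalized = rmse / norm_range, n = n)
}

#' Run one trait's LOSO-cross-validated boosted-tree analysis
#'
#' For each participant, fits a tuned boosted-tree regression on all other
#' participants' rows ([tune_and_fit()]) and predicts the held-out rows.
#' The per-fold seed is `seed + hash(participant)`, so results do not
#' depend on fold execution order. Cohort-level performance is reported
#' two ways: `mean_r2`, the average of the defined per-fold R-squared
#' values, and `pooled_r2`, the squared correlation between all held-out
#' predictions and observations pooled across folds (the stabler measure
#' when folds have only 1--6 rows).
#'
#' @param table Modelling table from [join_model_data()].
#' @param grid Hyperparameter grid.
#' @param seed Base seed.
#' @param norm_range RMSE normalization range; default the observed span of
#'   the outcome in `table`.
#' @param r2_method Passed to [evaluate_fold()].
#' @param importance Compute per-fold permutation importance on the
#'   training side and average across folds (slower).
#' @param n_repeats Permutation repeats per feature when `importance`.
#' @return List of class `loso_result`: `folds` (per-participant metrics
#'   and chosen hyperparameters), `predictions` (held-out observed and
#'   predicted per row), `mean_r2`, `pooled_r2`, `mean_rmse`,
#'   `mean_rmse_normalized`, `importance` (raw, or `NULL`), `norm_range`.
#' @export
run_loso <- function(table, grid = default_grid(reduced = TRUE), seed = 2012,
                     norm_range = NULL, r2_method = "cor",
                     importance = FALSE, n_repeats = 10) {
  if (is.null(norm_range)) {
    norm_range <- diff(range(table$outcome))
    if (norm_range == 0) norm_range <- 1
  }
  x_all <- as.matrix(table[predictor_columns()])
  y_all <- table$outcome
  folds <- loso_folds(table)

  fold_rows <- list()
  preds <- rep(NA_real_, nrow(table))
  imp_sum <- NULL
  for (id in names(folds)) {
    test <- folds[[id]]
    train <- setdiff(seq_len(nrow(table)), test)
    fseed <- fold_seed(seed, id)
    fit <- tune_and_fit(x_all[train, , drop = FALSE], y_all[train],
                        table$participant_id[train], grid, seed = fseed)
    p <- predict(fit$model, x_all[test, , drop = FALSE])
    preds[test] <- p
    m <- evaluate_fold(y_all[test], p, norm_range, r2_method)
    fold_rows[[id]] <- data.frame(
      participant_id = id, n_test = m$n, r2 = m$r2, rmse = m$rmse,
      rmse_normalized = m$rmse_normalized,
      nrounds = fit$params$nrounds, max_depth = fit$params$max_depth,
      eta = fit$params$eta, subsample = fit$params$subsample,
      colsample_bytree = fit$params$colsample_bytree,
      gamma = fit$params$gamma, min_child_weight = fit$params$min_child_weight,
      seed = fseed, stringsAsFactors = FALSE
    )
    if (importance) {
      imp <- permutation_importance(fit$model, x_all[train, , drop = FALSE],
                                    y_all[train], n_repeats = n_repeats,
                                    seed = fseed)
      imp_sum <- if (is.null(imp_sum)) imp else imp_sum + imp
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  rownames(folds_df) <- NULL
  r2s <- folds_df$r2[!is.na(folds_df$r2)]
  pooled <- if (sd(preds) > 0 && sd(y_all) > 0) cor(y_all, preds)^2 else 0
  structure(list(
    folds = folds_df,
    predictions = data.frame(participant_id = table$participant_id,
                             week = table$week, observed = y_all,
                             predicted = preds, stringsAsFactors = FALSE),
    mean_r2 = if (length(r2s)) mean(r2s) else NA_real_,
    pooled_r2 = pooled,
    mean_rmse = mean(folds_df$rmse),
    mean_rmse_normalized = mean(folds_df$rmse_normalized),
    importance = if (importance) imp_sum / length(folds) else NULL,
    norm_range = norm_range
  ), class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("LOSO boosted-tree result:", nrow(x$folds), "folds,",
      nrow(x$predictions), "person-weeks\n")
  cat(sprintf("  mean fold R2 (defined folds): %.3f\n", x$mean_r2))
  cat(sprintf("  pooled out-of-fold R2:        %.3f\n", x$pooled_r2))
  cat(sprintf("  mean fold RMSE:               %.3f (normalized %.3f)\n",
              x$mean_rmse, x$mean_rmse_normalized))
  invisible(x)
}

#' Consistently-informative participant flag
#'
#' A participant's five trait models are consistently informative when the
#' worst model still explains at least 5\% of the variance
#' (min R-squared >= 0.05, boundary inclusive) and the average normalized
#' RMSE across the five models does not exceed 25\% of the outcome range
#' (<= 0.25). Any undefined R-squared makes the flag `FALSE`.
#'
#' @param r2 Per-trait R-squared values for one participant.
#' @param rmse_normalized Per-trait normalized RMSE values.
#' @return Logical scalar.
#' @export
flag_informative <- function(r2, rmse_normalized) {
  if (any(is.na(r2)) || any(is.na(rmse_normalized))) return(FALSE)
  min(r2) >= 0.05 && mean(rmse_normalized) <= 0.25
}

#' Per-participant performance summary across the five trait models
#'
#' @param trait_results Named list of `loso_result` objects, one per trait.
#' @return Data.frame, one row per participant: min/max/mean R-squared and
#'   normalized RMSE across traits plus the informative flag, sorted by
#'   minimum R-squared (descending) then average normalized RMSE
#'   (ascending). Undefined per-trait R-squared propagates as `NA`
#'   min/max/avg (such participants sort last).
#' @export
summarize_participants <- function(trait_results) {
  ids <- sort(unique(unlist(lapply(trait_results, function(r) {
    r$folds$participant_id
  }))))
  rows <- lapply(ids, function(id) {
    r2 <- vapply(trait_results, function(r) {
      v <- r$folds$r2[r$folds$participant_id == id]
      if (length(v)) v else NA_real_
    }, numeric(1))
    nr <- vapply(trait_results, function(r) {
      v <- r$folds$rmse_normalized[r$folds$participant_id == id]
      if (length(v)) v else NA_real_
    }, numeric(1))
    data.frame(
      participant_id = id,
      r2_min = if (any(is.na(r2))) NA_real_ else min(r2),
      r2_max = if (any(is.na(r2))) NA_real_ else max(r2),
      r2_avg = if (any(is.na(r2))) NA_real_ else mean(r2),
      nrmse_min = min(nr), nrmse_max = max(nr), nrmse_avg = mean(nr),
      informative = flag_informative(r2, nr),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-xtfrm(out$r2_min), out$nrmse_avg, out$participant_id), ]
  rownames(out) <- NULL
  out
}

#' Comparator models under the same LOSO scheme
#'
#' Two simpler learners fitted per LOSO fold with library defaults: a
#' regularized (lasso) generalized linear model chosen by inner
#' cross-validated lambda, and a k-nearest-neighbour regression (k = 5).
#' Emits the same per-fold metrics as [run_loso()].
#'
#' @inheritParams run_loso
#' @return Named list of two `loso_result`-like lists (`glmnet`, `knn`).
#' @export
fit_comparators <- function(table, seed = 2012, norm_range = NULL,
                            r2_method = "cor") {
  if (is.null(norm_range)) {
    norm_range <- diff(range(table$outcome))
    if (norm_range == 0) norm_range <- 1
  }
  x_all <- as.matrix(table[predictor_columns()])
  y_all <- table$outcome
  folds <- loso_folds(table)
  run_one <- function(fit_fun) {
    fold_rows <- list()
    preds <- rep(NA_real_, nrow(table))
    for (id in names(folds)) {
      test <- folds[[id]]
      train <- setdiff(seq_len(nrow(table)), test)
      p <- fit_fun(x_all[train, , drop = FALSE], y_all[train],
                   x_all[test, , drop = FALSE], fold_seed(seed, id))
      preds[test] <- p
      m <- evaluate_fold(y_all[test], p, norm_range, r2_method)
      fold_rows[[id]] <- data.frame(participant_id = id, n_test = m$n,
                                    r2 = m$r2, rmse = m$rmse,
                                    rmse_normalized = m$rmse_normalized,
                                    stringsAsFactors = FALSE)
    }
    folds_df <- do.call(rbind, fold_rows)
    rownames(folds_df) <- NULL
    r2s <- folds_df$r2[!is.na(folds_df$r2)]
    list(folds = folds_df,
         predictions = data.frame(participant_id = table$participant_id,
                                  week = table$week, observed = y_all,
                                  predicted = preds),
         mean_r2 = if (length(r2s)) mean(r2s) else NA_real_,
         pooled_r2 = if (sd(preds) > 0) cor(y_all, preds)^2 else 0,
         mean_rmse = mean(folds_df$rmse),
         mean_rmse_normalized = mean(folds_df$rmse_normalized),
         norm_range = norm_range)
  }
  glmnet_fit <- function(xtr, ytr, xte, s) {
    cv <- local_seed(s, glmnet::cv.glmnet(xtr, ytr))
    as.numeric(predict(cv, xte, s = "lambda.min"))
  }
  knn_fit <- function(xtr, ytr, xte, s) {
    m <- caret::knnreg(xtr, ytr) # default k = 5
    as.numeric(predict(m, xte))
  }
  list(glmnet = run_one(glmnet_fit), knn = run_one(knn_fit))
}

# -- internal -----------------------------------------------------------------

fit_xgb <- function(x, y, params_row, seed, nthread = 1) {
  params <- list(
    objective = "reg:squarederror",
    max_depth = params_row$max_depth, eta = params_row$eta,
    gamma = params_row$gamma, subsample = params_row$subsample,
    colsample_bytree = params_row$colsample_bytree,
    min_child_weight = params_row$min_child_weight,
    nthread = nthread, seed = seed
  )
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
  local_seed(seed,
             xgboost::xgb.train(params, d, nrounds = params_row$nrounds,
                                verbose = 0))
}

# Stable per-participant seed offset: independent of fold order, bounded so
# base seeds up to ~2e9 stay valid 32-bit integers.
fold_seed <- function(base_seed, id) {
  h <- sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id))))
  as.integer((base_seed + h) %% .Machine$integer.max)
}
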