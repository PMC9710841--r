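make_features <- function(ids, weeks) {
  grid <- expand.grid(participant_id = ids, week = weeks,
                      stringsAsFactors = FALSE)
  set.seed(nrow(grid))
  for (f in predictor_columns()) {
    if (f != "week") grid[[f]] <- runif(nrow(grid))
  }
  grid
}

make_outcomes <- function(ids, weeks, value = NULL) {
  grid <- expand.grid(participant_id = ids, week = weeks,
                      stringsAsFactors = FALSE)
  set.seed(nrow(grid) + 1)
  for (tr in c("extra", "agree", "consc", "stabl", "open")) {
    grid[[tr]] <- if (is.null(value)) runif(nrow(grid), 0, 3) else value
  }
  grid
}

test_that("join keeps exactly the shared person-weeks", {
  f <- make_features(c("A", "B"), 1:2)
  o <- make_outcomes(c("A", "B"), 1:2)
  o <- o[!(o$participant_id == "B" & o$week == 2), ]
  suppressMessages(tab <- join_model_data(f, o, "extra"))
  expect_equal(nrow(tab), 3)
  # join is order independent
  suppressMessages(tab2 <- join_model_data(f[sample(nrow(f)), ],
                                           o[sample(nrow(o)), ], "extra"))
  expect_equal(tab2, tab)
  # undefined outcomes drop their rows
  o$extra[1] <- NA
  suppressMessages(tab3 <- join_model_data(f, o, "extra"))
  expect_equal(nrow(tab3), 2)
  # disjoint keys are fatal
  o2 <- make_outcomes(c("X", "Y"), 1:2)
  suppressMessages(expect_error(join_model_data(f, o2, "extra"), "no usable"))
})

test_that("LOSO folds partition rows by participant", {
  for (n in c(2, 5, 9)) {
    f <- make_features(LETTERS[1:n], 1:3)
    o <- make_outcomes(LETTERS[1:n], 1:3)
    suppressMessages(tab <- join_model_data(f, o, "agree"))
    folds <- loso_folds(tab)
    expect_length(folds, n)
    idx <- sort(unname(unlist(folds)))
    expect_equal(idx, seq_len(nrow(tab)))
    for (id in names(folds)) {
      expect_setequal(tab$participant_id[folds[[id]]], id)
      expect_false(id %in% tab$participant_id[-folds[[id]]])
    }
  }
  expect_error(loso_folds(data.frame(participant_id = "A")), "at least 2")
})

test_that("grid search selects by inner RMSE with deterministic refits", {
  co <- simulate_cohort(small_config(seed = 51))
  tab <- cohort_table(co)
  x <- as.matrix(tab[predictor_columns()])
  one <- default_grid(reduced = TRUE)[3, , drop = FALSE]
  fit <- tune_and_fit(x, tab$outcome, tab$participant_id, one, seed = 9)
  expect_equal(fit$params, one) # single candidate is always chosen
  fit2 <- tune_and_fit(x, tab$outcome, tab$participant_id, one, seed = 9)
  expect_identical(predict(fit$model, x), predict(fit2$model, x))
  # multi-point grid: winner is the inner-RMSE minimum, first on ties
  grid <- default_grid(reduced = TRUE)
  fit3 <- tune_and_fit(x, tab$outcome, tab$participant_id, grid, seed = 9)
  expect_equal(fit3$params,
               grid[which.min(fit3$inner_rmse), , drop = FALSE])
})

test_that("fold metrics follow the R-squared and normalization conventions", {
  obs <- c(0.2, 0.8, 1.4, 2.0)
  m <- evaluate_fold(obs, obs, norm_range = 2)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  # constant predictions: undefined R2, RMSE still defined
  m <- evaluate_fold(obs, rep(1, 4), norm_range = 2)
  expect_true(is.na(m$r2))
  expect_equal(m$rmse, sqrt(mean((obs - 1)^2)))
  # a single test row defines RMSE but not R2
  m <- evaluate_fold(1.5, 1.1, norm_range = 2)
  expect_true(is.na(m$r2))
  expect_equal(m$rmse, 0.4)
  expect_equal(m$rmse_normalized, 0.2)
  # scale-free R2: perfectly anti-correlated predictions still score 1
  m <- evaluate_fold(obs, -obs, norm_range = 2)
  expect_equal(m$r2, 1)
  # sum-of-squares alternative does not forgive the sign flip
  m <- evaluate_fold(obs, -obs, norm_range = 2, r2_method = "ss")
  expect_equal(m$r2, 0)
})

test_that("the informative flag applies both thresholds inclusively", {
  expect_true(flag_informative(c(0.05, 0.3, 0.5, 0.2, 0.9),
                               rep(0.25, 5)))
  expect_false(flag_informative(c(0.04, 0.3, 0.5, 0.2, 0.9), rep(0.1, 5)))
  expect_false(flag_informative(rep(0.5, 5), c(0.3, 0.3, 0.3, 0.2, 0.2)))
  expect_false(flag_informative(c(NA, 0.5, 0.5, 0.5, 0.5), rep(0.1, 5)))
})

test_that("training is blind to the held-out participant's outcomes", {
  co <- simulate_cohort(small_config(seed = 61, n_participants = 8))
  tab <- cohort_table(co)
  grid1 <- default_grid(reduced = TRUE)[1, , drop = FALSE]
  res1 <- run_loso(tab, grid = grid1, seed = 3)
  # scramble one participant's outcomes; only that fold's metrics may move
  tab2 <- tab
  victim <- unique(tab2$participant_id)[1]
  rows <- which(tab2$participant_id == victim)
  tab2$outcome[rows] <- rev(tab2$outcome[rows]) + 0.25
  res2 <- run_loso(tab2, grid = grid1, seed = 3)
  expect_equal(res2$predictions$predicted[rows],
               res1$predictions$predicted[rows])
  # and the full run is bit-identical on repeat
  res3 <- run_loso(tab, grid = grid1, seed = 3)
  expect_identical(res1$predictions, res3$predictions)
  expect_identical(res1$folds, res3$folds)
})

test_that("fold seeds derive from participant ids, not execution order", {
  expect_equal(fold_seed(100, "506"), fold_seed(100, "506"))
  expect_false(fold_seed(100, "506") == fold_seed(100, "507"))
  expect_lt(fold_seed(2e9, "554"), .Machine$integer.max)
})

test_that("planted signal is recovered and pure noise is not", {
  co <- simulate_cohort(small_config(seed = 71, n_participants = 14,
                                     n_weeks = 4))
  tab <- cohort_table(co)
  grid1 <- default_grid(reduced = TRUE)[2, , drop = FALSE]
  res <- run_loso(tab, grid = grid1, seed = 5)
  expect_gt(res$pooled_r2, 0.3)
  # same cohort, outcomes replaced by noise
  tabn <- tab
  tabn$outcome <- local({set.seed(1); runif(nrow(tab), 0, 2)})
  resn <- run_loso(tabn, grid = grid1, seed = 5)
  expect_lt(resn$pooled_r2, 0.15)
})

test_that("comparator models share fold keys and handle canonical cases", {
  f <- make_features(LETTERS[1:8], 1:4)
  o <- make_outcomes(LETTERS[1:8], 1:4)
  # perfectly linear outcome: the penalized linear model nails it
  o$extra <- 2 * f$efficiency[match(paste(o$participant_id, o$week),
                                    paste(f$participant_id, f$week))] + 1
  suppressMessages(tab <- join_model_data(f, o, "extra"))
  # small folds make cv.glmnet warn about its own grouping default
  suppressWarnings(comp <- fit_comparators(tab, seed = 13))
  expect_gt(comp$glmnet$pooled_r2, 0.98)
  expect_equal(comp$knn$folds$participant_id, comp$glmnet$folds$participant_id)
  expect_true(all(comp$knn$folds$rmse >= 0))
})

test_that("participant summary ranks by minimum R2 then normalized error", {
  mk <- function(ids, r2, nr) {
    list(folds = data.frame(participant_id = ids, n_test = 3, r2 = r2,
                            rmse = nr, rmse_normalized = nr))
  }
  traits <- lapply(1:5, function(i) {
    mk(c("A", "B", "C"), c(0.5, 0.08, 0.08), c(0.1, 0.2, 0.1))
  })
  names(traits) <- c("extra", "agree", "consc", "stabl", "open")
  s <- summarize_participants(traits)
  expect_equal(s$participant_id, c("A", "C", "B")) # tie on r2_min -> nrmse
  expect_true(all(s$informative))
  traits$open$folds$r2[1] <- NA
  s2 <- summarize_participants(traits)
  expect_true(is.na(s2$r2_min[s2$participant_id == "A"]))
  expect_false(s2$informative[s2$participant_id == "A"])
  expect_equal(s2$participant_id[3], "A") # undefined R2 sorts last
})
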