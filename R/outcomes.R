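#' Root mean square of successive differences
#'
#' The moment-to-moment variability of an ordered measurement series:
#' \deqn{\mathrm{RMSSD} = \sqrt{\frac{\sum_{i=1}^{N-1} (x_i - x_{i+1})^2}{N - 1}}}
#' where \eqn{N} is the number of measurements and \eqn{x_i} the value at
#' occasion \eqn{i}. Translation invariant and linear in scale; zero for a
#' constant series. Undefined (`NA`) for fewer than two measurements.
#'
#' @param x Numeric vector in chronological order.
#' @return Non-negative scalar, or `NA_real_` when `length(x) < 2`.
#' @examples
#' rmssd(c(1, 4, 2, 7)) # sqrt((9 + 4 + 25) / 3)
#' @export
rmssd <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) return(NA_real_)
  sqrt(sum(diff(x)^2) / (n - 1))
}

#' Per person-week personality-state variability outcomes
#'
#' For every participant, week and trait, orders that week's EMA responses
#' by timestamp (file order breaks ties) and reduces them to one RMSSD
#' value. Responses on different days of the same week form a single
#' series; missed prompts simply leave longer gaps, with no imputation.
#' Weeks with fewer than two responses give `NA` for all five traits.
#'
#' @param ema EMA records with a `week` column (see [split_work_weeks()]).
#' @return Data.frame `participant_id`, `week`, and one RMSSD column per
#'   trait (`extra`, `agree`, `consc`, `stabl`, `open`).
#' @export
build_outcome_table <- function(ema) {
  stopifnot(all(c("participant_id", "week", TRAITS) %in% names(ema)))
  keys <- unique(ema[c("participant_id", "week")])
  keys <- keys[order(keys$participant_id, keys$week), , drop = FALSE]
  out <- keys
  for (tr in TRAITS) out[[tr]] <- NA_real_
  for (i in seq_len(nrow(keys))) {
    rows <- ema[ema$participant_id == keys$participant_id[i] &
                  ema$week == keys$week[i], , drop = FALSE]
    rows <- rows[order(rows$timestamp), , drop = FALSE]
    for (tr in TRAITS) out[[tr]][i] <- rmssd(rows[[tr]])
  }
  rownames(out) <- NULL
  out
}

#' Cohort summary of weekly outcomes
#'
#' Median, minimum and maximum RMSSD across participants, per week and
#' trait. The median of an even count uses midpoint interpolation.
#'
#' @param outcomes Table from [build_outcome_table()].
#' @return Long data.frame `week`, `trait`, `median`, `min`, `max`
#'   (traits in canonical order), `NA` rows excluded per trait.
#' @export
summarize_outcomes <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  res <- list()
  for (w in sort(unique(outcomes$week))) {
    sub <- outcomes[outcomes$week == w, , drop = FALSE]
    for (tr in TRAITS) {
      v <- sub[[tr]][!is.na(sub[[tr]])]
      res[[length(res) + 1]] <- data.frame(
        week = w, trait = tr,
        median = if (length(v)) median(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
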