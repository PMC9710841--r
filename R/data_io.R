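#' Work-week calendar
#'
#' Build a table of consecutive Monday--Friday work weeks starting from a
#' given Monday. Weeks are calendar-date based and inclusive at both ends;
#' the intervening weekend days belong to no week.
#'
#' @param start_monday `Date` (or string coercible to one) that must fall on
#'   a Monday; the first day of week 1.
#' @param n_weeks Number of consecutive work weeks.
#' @return A data.frame with columns `week` (1-based integer index),
#'   `start_date` (Monday) and `end_date` (the following Friday).
#' @examples
#' work_weeks("2012-01-30", 6)
#' @export
work_weeks <- function(start_monday, n_weeks) {
  start_monday <- as.Date(start_monday)
  if (format(start_monday, "%u") != "1") {
    stop("start_monday must be a Monday, got ", format(start_monday, "%A"))
  }
  if (n_weeks < 1) stop("n_weeks must be >= 1")
  starts <- start_monday + 7 * (seq_len(n_weeks) - 1)
  data.frame(
    week = seq_len(n_weeks),
    start_date = starts,
    end_date = starts + 4
  )
}

#' Parse a directed badge interaction log
#'
#' Reads a CSV of device-detected one-on-one interaction events, one row per
#' detection: a timestamp, the id of the participant whose detector produced
#' the record, and the id of the participant detected. Malformed rows,
#' self-detections, weekend records and records outside the study window are
#' dropped, with the counts reported in a single warning.
#'
#' @param path Path to the CSV log.
#' @param window Optional length-2 vector of dates; records outside
#'   `[window[1], window[2]]` are dropped.
#' @param col_map Named character vector mapping the canonical column names
#'   `timestamp`, `logger_id`, `detected_id` to the header names used in the
#'   file. Defaults to the identity mapping.
#' @return A data.frame with columns `timestamp` (POSIXct, UTC),
#'   `logger_id`, `detected_id` (character), sorted by timestamp.
#' @export
parse_interaction_log <- function(path, window = NULL,
                                  col_map = c(timestamp = "timestamp",
                                              logger_id = "logger_id",
                                              detected_id = "detected_id")) {
  raw <- read_log_csv(path, col_map,
                      c("timestamp", "logger_id", "detected_id"))
  ts <- parse_timestamp(raw$timestamp)
  rec <- data.frame(
    timestamp = ts,
    logger_id = as.character(raw$logger_id),
    detected_id = as.character(raw$detected_id),
    stringsAsFactors = FALSE
  )

  n0 <- nrow(rec)
  bad_ts <- is.na(rec$timestamp) | !nzchar(rec$logger_id) |
    !nzchar(rec$detected_id) | is.na(rec$logger_id) | is.na(rec$detected_id)
  rec <- rec[!bad_ts, , drop = FALSE]
  self <- rec$logger_id == rec$detected_id
  rec <- rec[!self, , drop = FALSE]
  wk <- in_window(rec$timestamp, window)
  rec <- rec[wk, , drop = FALSE]
  weekend <- format(as.Date(rec$timestamp, tz = "UTC"), "%u") %in% c("6", "7")
  rec <- rec[!weekend, , drop = FALSE]

  report_drops(n0, nrow(rec),
               malformed = sum(bad_ts), self_loops = sum(self),
               out_of_window = sum(!wk), weekend = sum(weekend))
  if (nrow(rec) == 0) stop("no valid interaction records in ", path)
  rec <- rec[order(rec$timestamp), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Parse an EMA personality-state log
#'
#' Reads a CSV of momentary self-reports: a timestamp, a participant id and
#' five personality-state scores (extraversion, agreeableness,
#' conscientiousness, emotional stability, openness), each on a 1--7 Likert
#' scale in half-point increments (the mean of two item responses). Rows with
#' any score outside \[1, 7\] are dropped with a warning.
#'
#' @param path Path to the CSV log.
#' @param window Optional length-2 date vector; see [parse_interaction_log()].
#' @param col_map Named character vector mapping canonical names
#'   (`timestamp`, `participant_id`, `extra`, `agree`, `consc`, `stabl`,
#'   `open`) to file header names.
#' @return A data.frame with columns `timestamp`, `participant_id` and the
#'   five trait scores, sorted by (participant, timestamp). Ties in timestamp
#'   keep file order.
#' @export
parse_ema_log <- function(path, window = NULL,
                          col_map = c(timestamp = "timestamp",
                                      participant_id = "participant_id",
                                      extra = "extra", agree = "agree",
                                      consc = "consc", stabl = "stabl",
                                      open = "open")) {
  canonical <- c("timestamp", "participant_id", TRAITS)
  raw <- read_log_csv(path, col_map, canonical)
  rec <- data.frame(
    timestamp = parse_timestamp(raw$timestamp),
    participant_id = as.character(raw$participant_id),
    stringsAsFactors = FALSE
  )
  for (tr in TRAITS) rec[[tr]] <- suppressWarnings(as.numeric(raw[[tr]]))

  n0 <- nrow(rec)
  scores <- as.matrix(rec[TRAITS])
  bad_ts <- is.na(rec$timestamp) | is.na(rec$participant_id) |
    !nzchar(rec$participant_id)
  out_of_range <- apply(is.na(scores) | scores < 1 | scores > 7, 1, any)
  keep <- !bad_ts & !out_of_range
  wk <- in_window(rec$timestamp, window)
  rec <- rec[keep & wk, , drop = FALSE]
  report_drops(n0, nrow(rec),
               malformed = sum(bad_ts),
               score_out_of_range = sum(out_of_range & !bad_ts),
               out_of_window = sum(!wk & keep))
  if (nrow(rec) == 0) stop("no valid EMA records in ", path)
  rec <- rec[order(rec$participant_id, rec$timestamp), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Assign records to work weeks
#'
#' Adds a `week` column to a record table according to a work-week calendar.
#' A record belongs to week *w* when its calendar date lies in
#' `[start_date, end_date]` of that week (inclusive both ends; a Monday
#' 00:00 timestamp belongs to that Monday's week). Records outside all weeks
#' are dropped with a warning.
#'
#' @param records Data.frame with a POSIXct `timestamp` column.
#' @param weeks Work-week calendar from [work_weeks()].
#' @return `records` with an integer `week` column appended.
#' @export
split_work_weeks <- function(records, weeks) {
  stopifnot(is.data.frame(records), "timestamp" %in% names(records))
  d <- as.Date(records$timestamp, tz = "UTC")
  wk <- rep(NA_integer_, length(d))
  for (i in seq_len(nrow(weeks))) {
    hit <- d >= weeks$start_date[i] & d <= weeks$end_date[i]
    wk[hit] <- weeks$week[i]
  }
  dropped <- sum(is.na(wk))
  if (dropped > 0) {
    warning(dropped, " record(s) outside all work weeks dropped")
  }
  out <- records[!is.na(wk), , drop = FALSE]
  out$week <- wk[!is.na(wk)]
  rownames(out) <- NULL
  out
}

#' Write and read tabular pipeline artifacts
#'
#' All intermediate tables are written as plain CSV with a header and read
#' back with type restoration for the timestamp column, so that a write/read
#' round trip is lossless.
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @return `read_table_csv` returns the data.frame; `write_table_csv`
#'   returns `path` invisibly.
#' @export
write_table_csv <- function(x, path) {
  out <- x
  if ("timestamp" %in% names(out)) {
    out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  for (nm in names(out)) if (inherits(out[[nm]], "Date")) {
    out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @param id_cols Columns to force to character on read (ids survive numeric
#'   round trips unchanged).
#' @export
read_table_csv <- function(path, id_cols = c("participant_id", "logger_id",
                                             "detected_id")) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp" %in% names(x)) x$timestamp <- parse_timestamp(x$timestamp)
  for (nm in intersect(id_cols, names(x))) x[[nm]] <- as.character(x[[nm]])
  x
}

# -- internal helpers ---------------------------------------------------------

read_log_csv <- function(path, col_map, canonical) {
  if (!file.exists(path)) stop("cannot read log file: ", path)
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                  error = function(e) stop("cannot read log file: ", path,
                                           " (", conditionMessage(e), ")"))
  missing_map <- setdiff(canonical, names(col_map))
  if (length(missing_map) > 0) {
    stop("col_map lacks entries for: ", paste(missing_map, collapse = ", "))
  }
  missing_cols <- setdiff(unname(col_map[canonical]), names(raw))
  if (length(missing_cols) > 0) {
    stop("log file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- raw[unname(col_map[canonical])]
  names(out) <- canonical
  out
}

# Timestamps are ISO-8601, timezone-naive (single-site study); parsed as UTC.
# Formats are tried element-wise so one malformed row cannot poison the batch.
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

in_window <- function(ts, window) {
  if (is.null(window)) return(rep(TRUE, length(ts)))
  d <- as.Date(ts, tz = "UTC")
  !is.na(d) & d >= as.Date(window[1]) & d <= as.Date(window[2])
}

report_drops <- function(n0, n1, ...) {
  drops <- c(...)
  drops <- drops[drops > 0]
  if (length(drops) > 0) {
    warning("dropped ", n0 - n1, "/", n0, " rows (",
            paste(names(drops), drops, sep = "=", collapse = ", "), ")",
            call. = FALSE)
  }
  invisible(NULL)
}
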