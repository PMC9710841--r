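#' Synthetic cohort configuration
#'
#' Parameters of the generative model used to emulate a badge-plus-EMA
#' workplace study. Contacts follow a stochastic block model: each
#' unordered pair of participants accrues a Poisson number of true contacts
#' per workday at a rate set by whether the two share a community block,
#' modulated by a weekly activity factor and per person-week engagement
#' factors (both log-normal) so that networks — like real workplace
#' networks — differ from week to week and person to person. Each true
#' contact is logged independently by each of the two badges with
#' probability `1 - detector_thinning`, creating the directional count
#' discrepancies the minimum-count reconciliation rule is designed for.
#'
#' EMA responses are generated three times per workday at fixed clock
#' times. Per participant, week and trait, the latent state performs a
#' first-order random walk around the trait mean with innovation scale
#' \eqn{\sigma = \max(\sigma_0 + \beta z, 0.05)}, where `z` is the
#' participant's within-week standardized value of the driver network
#' feature — the planted ground-truth link the pipeline should recover.
#' Isolated participants get the baseline scale. Responses are the latent
#' state plus measurement noise, rounded to the half-point 1--7 grid.
#'
#' @param n_participants Cohort size.
#' @param n_weeks Number of Monday--Friday work weeks.
#' @param start_monday First Monday of the study window.
#' @param n_blocks Number of community blocks (sizes as equal as possible).
#' @param within_rate,between_rate Expected true contacts per pair per
#'   workday within / between blocks.
#' @param week_rate_sd,person_week_sd Log-scale SDs of the weekly and
#'   person-week activity factors.
#' @param detector_thinning Per-direction probability that a badge misses a
#'   contact.
#' @param ema_times Clock times of the daily prompts.
#' @param trait_mean,trait_sd Population mean and SD of the per-person
#'   trait means (clipped to \[2, 6\]).
#' @param sigma_baseline Baseline innovation scale \eqn{\sigma_0}.
#' @param driver Name of the network feature driving volatility (one of
#'   [predictor_columns()] less `week`).
#' @param coefficient Planted effect \eqn{\beta} of the standardized driver
#'   on \eqn{\sigma}; 0 gives a null cohort.
#' @param response_noise SD of the measurement noise added to each
#'   response.
#' @param seed Root seed; all streams derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_participants = 54, n_weeks = 6,
                       start_monday = "2012-01-30", n_blocks = 4,
                       within_rate = 4, between_rate = 0.8,
                       week_rate_sd = 0.2, person_week_sd = 0.4,
                       detector_thinning = 0.15,
                       ema_times = c("11:00", "14:00", "17:00"),
                       trait_mean = 4.25, trait_sd = 0.7,
                       sigma_baseline = 0.3, driver = "efficiency",
                       coefficient = 0.5, response_noise = 0.1,
                       seed = 2012) {
  stopifnot(n_participants >= 2, n_weeks >= 1,
            within_rate >= 0, between_rate >= 0,
            detector_thinning >= 0, detector_thinning <= 1,
            sigma_baseline > 0, driver %in% FEATURE_COLUMNS)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one week of badge interaction records
#'
#' @param config A [sim_config()].
#' @param week Week index (1-based).
#' @return Data.frame of directed interaction records (`timestamp`,
#'   `logger_id`, `detected_id`), sorted by timestamp.
#' @export
simulate_interactions <- function(config, week) {
  ch <- cohort_params(config)
  weeks <- work_weeks(config$start_monday, config$n_weeks)
  monday <- weeks$start_date[weeks$week == week]
  ids <- ch$ids
  n <- length(ids)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same_block <- ch$block[pair[, 1]] == ch$block[pair[, 2]]
  base_rate <- ifelse(same_block, config$within_rate, config$between_rate)

  local_seed(config$seed + 7919 * week + 1, {
    recs <- list()
    p_log <- 1 - config$detector_thinning
    for (d in 0:4) {
      rate <- base_rate * ch$week_mult[week] *
        sqrt(ch$pw_mult[pair[, 1], week] * ch$pw_mult[pair[, 2], week])
      n_true <- rpois(nrow(pair), rate)
      c_ab <- rbinom(nrow(pair), n_true, p_log)
      c_ba <- rbinom(nrow(pair), n_true, p_log)
      day <- monday + d
      for (dir in 1:2) {
        cnt <- if (dir == 1) c_ab else c_ba
        keep <- cnt > 0
        if (!any(keep)) next
        logger <- ids[pair[keep, dir]]
        detected <- ids[pair[keep, 3 - dir]]
        reps <- cnt[keep]
        secs <- runif(sum(reps), 9 * 3600, 18 * 3600)
        recs[[length(recs) + 1]] <- data.frame(
          timestamp = as.POSIXct(as.character(day), tz = "UTC") +
            round(secs),
          logger_id = rep(logger, reps),
          detected_id = rep(detected, reps),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, recs)
    if (is.null(out)) {
      out <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                        logger_id = character(), detected_id = character())
    }
    out <- out[order(out$timestamp, out$logger_id, out$detected_id), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate one week of EMA responses
#'
#' @param config A [sim_config()].
#' @param network The weekly network built from that week's simulated
#'   interactions (drives the planted volatility link).
#' @param week Week index.
#' @return List with `ema` (records data.frame) and `truth` (per
#'   participant and trait: planted `sigma_true`, `driver_value`,
#'   standardized `driver_z`).
#' @export
simulate_ema <- function(config, network, week) {
  ch <- cohort_params(config)
  weeks <- work_weeks(config$start_monday, config$n_weeks)
  monday <- weeks$start_date[weeks$week == week]
  ids <- ch$ids

  drv <- driver_values(network, config$driver)
  z <- rep(0, length(ids))
  names(z) <- ids
  present <- intersect(ids, names(drv))
  if (length(present) >= 2 && sd(drv[present]) > 0) {
    z[present] <- (drv[present] - mean(drv[present])) / sd(drv[present])
  }
  dval <- rep(NA_real_, length(ids))
  names(dval) <- ids
  dval[present] <- drv[present]

  slot_times <- as.difftime(paste0(config$ema_times, ":00"), units = "secs")
  stamps <- as.POSIXct(unlist(lapply(0:4, function(d) {
    as.character(as.POSIXct(as.character(monday + d), tz = "UTC") +
                   as.numeric(slot_times, units = "secs"))
  })), tz = "UTC")
  n_slots <- length(stamps)

  local_seed(config$seed + 7919 * week + 2, {
    ema_rows <- list()
    truth_rows <- list()
    for (i in seq_along(ids)) {
      scores <- matrix(NA_real_, n_slots, length(TRAITS))
      for (ti in seq_along(TRAITS)) {
        beta <- planted_coefficient(config, TRAITS[ti])
        sigma <- max(config$sigma_baseline + beta * z[i], 0.05)
        latent <- numeric(n_slots)
        latent[1] <- clamp17(ch$trait_means[i, ti] + rnorm(1, 0, sigma))
        for (s in 2:n_slots) {
          latent[s] <- clamp17(latent[s - 1] + rnorm(1, 0, sigma))
        }
        obs <- latent + rnorm(n_slots, 0, config$response_noise)
        scores[, ti] <- clamp17(round(obs * 2) / 2)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          participant_id = ids[i], week = week, trait = TRAITS[ti],
          sigma_true = sigma, driver_value = dval[ids[i]],
          driver_z = z[i], coefficient = beta, stringsAsFactors = FALSE
        )
      }
      df <- data.frame(timestamp = stamps, participant_id = ids[i],
                       stringsAsFactors = FALSE)
      for (ti in seq_along(TRAITS)) df[[TRAITS[ti]]] <- scores[, ti]
      ema_rows[[length(ema_rows) + 1]] <- df
    }
    ema <- do.call(rbind, ema_rows)
    ema <- ema[order(ema$participant_id, ema$timestamp), ]
    rownames(ema) <- NULL
    list(ema = ema, truth = do.call(rbind, truth_rows))
  })
}

#' Simulate a full multi-week cohort
#'
#' Chains [simulate_interactions()], [build_weekly_network()] and
#' [simulate_ema()] across all weeks. The emitted logs are in exactly the
#' dialect [parse_interaction_log()] and [parse_ema_log()] read, and the
#' whole object is a deterministic function of the configuration (the
#' root seed included).
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `interactions`, `ema`,
#'   `ground_truth` (all data.frames), `networks` (list of weekly graphs),
#'   `weeks` (calendar), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  weeks <- work_weeks(config$start_monday, config$n_weeks)
  interactions <- list()
  emas <- list()
  truths <- list()
  networks <- list()
  for (w in weeks$week) {
    rec <- simulate_interactions(config, w)
    net <- build_weekly_network(rec, week_index = w)
    sim <- simulate_ema(config, net, w)
    interactions[[w]] <- rec
    networks[[as.character(w)]] <- net
    emas[[w]] <- sim$ema
    truths[[w]] <- sim$truth
  }
  structure(list(
    interactions = do.call(rbind, interactions),
    ema = do.call(rbind, emas),
    ground_truth = do.call(rbind, truths),
    networks = networks, weeks = weeks, config = config
  ), class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits `interactions.csv` and `ema.csv` in the input dialect of the
#' parsers, `ground_truth.csv`, and the configuration echoed as
#' `sim_config.yaml`. Byte-identical across runs with the same
#' configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(cohort$interactions, file.path(dir, "interactions.csv"))
  write_table_csv(cohort$ema, file.path(dir, "ema.csv"))
  write_table_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  cfg <- unclass(cohort$config)
  cfg$start_monday <- as.character(cfg$start_monday)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

# -- internal -----------------------------------------------------------------

# Cohort-level latent parameters (blocks, trait means, activity factors),
# deterministic given the config.
cohort_params <- function(config) {
  n <- config$n_participants
  ids <- as.character(500 + seq_len(n))
  block <- sort(rep_len(seq_len(config$n_blocks), n))
  local_seed(config$seed + 1, {
    trait_means <- matrix(
      pmin(6, pmax(2, rnorm(n * length(TRAITS), config$trait_mean,
                            config$trait_sd))),
      n, length(TRAITS)
    )
    week_mult <- exp(rnorm(config$n_weeks, 0, config$week_rate_sd))
    pw_mult <- matrix(exp(rnorm(n * config$n_weeks, 0,
                                config$person_week_sd)),
                      n, config$n_weeks)
    list(ids = ids, block = block, trait_means = trait_means,
         week_mult = week_mult, pw_mult = pw_mult)
  })
}

# Value of one network feature for every node of a weekly network.
driver_values <- function(network, driver) {
  if (igraph::vcount(network) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  fm <- assemble_feature_matrix(stats::setNames(list(network), "1"))
  stats::setNames(fm[[driver]], fm$participant_id)
}

planted_coefficient <- function(config, trait) {
  beta <- config$coefficient
  if (!is.null(names(beta))) {
    if (!trait %in% names(beta)) return(0)
    return(unname(beta[trait]))
  }
  beta
}

clamp17 <- function(x) pmin(7, pmax(1, x))
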