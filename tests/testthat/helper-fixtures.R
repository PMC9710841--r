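# Shared fixture builders: tiny named graphs, random weighted graphs (both as
# igraph objects and as the plain weight matrices the oracles consume), and
# small simulated cohorts sized for fast model tests.

g_from_edges <- function(from, to, weight = 1) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to,
               weight = rep_len(weight, length(from))),
    directed = FALSE
  )
}

g_star <- function(k = 4) g_from_edges(rep("h", k), letters[seq_len(k)])

g_triangle <- function() g_from_edges(c("a", "b", "a"), c("b", "c", "c"))

g_path3 <- function() g_from_edges(c("a", "b"), c("b", "c"))

# Two 4-cliques joined by a single unit edge.
g_barbell <- function() {
  cl <- t(combn(4, 2))
  g_from_edges(
    c(paste0("a", cl[, 1]), paste0("b", cl[, 1]), "a1"),
    c(paste0("a", cl[, 2]), paste0("b", cl[, 2]), "b1")
  )
}

# Random connected weighted graph; returns both representations. Continuous
# weights keep modularity optima unique almost surely.
random_weighted_graph <- function(n, p = NULL, wmin = 0.5, wmax = 10) {
  if (is.null(p)) p <- runif(1, 0.4, 0.9)
  repeat {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- runif(n * (n - 1) / 2) < p
    A <- A + t(A)
    W <- A * matrix(runif(n * n, wmin, wmax), n, n)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    dimnames(W) <- list(paste0("n", 1:n), paste0("n", 1:n))
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::is_connected(g)) return(list(W = W, g = g))
  }
}

# Interaction records from explicit directed counts (timestamps all Monday).
records_from_counts <- function(logger, detected, n,
                                day = as.Date("2012-01-30")) {
  data.frame(
    timestamp = as.POSIXct(as.character(day), tz = "UTC") + 3600 * 10 +
      seq_len(sum(n)),
    logger_id = rep(logger, n),
    detected_id = rep(detected, n),
    stringsAsFactors = FALSE
  )
}

# Small, fast cohort for model-level tests.
small_config <- function(seed = 2012, n_participants = 10, n_weeks = 2, ...) {
  sim_config(n_participants = n_participants, n_weeks = n_weeks,
             n_blocks = 2, within_rate = 3, seed = seed, ...)
}

# Modelling table for one trait from a simulated cohort.
cohort_table <- function(cohort, trait = "extra") {
  fm <- assemble_feature_matrix(cohort$networks)
  ema <- split_work_weeks(cohort$ema, cohort$weeks)
  oc <- build_outcome_table(ema)
  suppressMessages(join_model_data(fm, oc, trait))
}

# Seeded shuffle that leaves the ambient RNG stream alone afterwards.
local_shuffle <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x[sample(length(x))]
}
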