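#' All-pairs shortest path distances
#'
#' Distances between every pair of nodes under one of two named schemes:
#' `"inverse-weight"` treats each edge as having length `1/weight`, so that
#' frequent contact means "close"; `"hop"` ignores weights and counts edges.
#' Unreachable pairs are `Inf`.
#'
#' @param net Weighted igraph graph.
#' @param scheme `"inverse-weight"` or `"hop"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = vertex
#'   names.
#' @export
shortest_paths_matrix <- function(net, scheme = c("inverse-weight", "hop")) {
  scheme <- match.arg(scheme)
  w <- if (scheme == "inverse-weight") 1 / igraph::E(net)$weight else NA
  igraph::distances(net, weights = w)
}

#' Community detection by modularity maximization
#'
#' Partitions a weighted network into subcommunities by maximizing
#' weighted modularity at resolution 1. At cohort scale the multi-level
#' (Louvain) heuristic is used, restarted `restarts` times from the seeded
#' RNG with the highest-modularity partition kept; for small graphs
#' (`<= n_exact` nodes) the exact integer-programming maximizer is used
#' instead, since the greedy heuristic can miss the optimum on graphs where
#' exact search is cheap. Deterministic for a fixed seed.
#'
#' @param net Nonempty weighted igraph graph.
#' @param seed Integer RNG seed (default 2012).
#' @param n_exact Maximum order for the exact maximizer.
#' @param restarts Louvain restarts at larger orders.
#' @return List with `membership` (named integer vector), `n_communities`,
#'   `modularity`, and `seed`.
#' @export
detect_communities <- function(net, seed = 2012, n_exact = 10, restarts = 10) {
  stopifnot(igraph::vcount(net) > 0)
  w <- igraph::E(net)$weight
  if (igraph::vcount(net) <= n_exact) {
    cl <- igraph::cluster_optimal(net, weights = w)
  } else {
    cl <- local_seed(seed, {
      best <- NULL
      best_q <- -Inf
      for (r in seq_len(restarts)) {
        cand <- igraph::cluster_louvain(net, weights = w)
        q <- igraph::modularity(net, igraph::membership(cand), weights = w)
        if (q > best_q + 1e-12) {
          best_q <- q
          best <- cand
        }
      }
      best
    })
  }
  memb <- igraph::membership(cl)
  names(memb) <- igraph::V(net)$name
  list(
    membership = memb,
    n_communities = length(unique(memb)),
    modularity = igraph::modularity(net, memb, weights = w),
    seed = seed
  )
}

#' Global structural features of a weekly network
#'
#' Nine whole-network quantities: order (number of nodes), size (number of
#' undirected ties), number of ordered pairs `n(n-1)`, density, diameter
#' (longest hop-count geodesic on the largest connected component),
#' geodesic distance (mean inverse-weight shortest path over connected
#' pairs), transitivity (closed over connected triplets), degree
#' centralization \eqn{\sum_i (d_{max} - d_i) / (n - 1)} with unweighted
#' degrees, and the number of subcommunities of the modularity partition.
#'
#' @param net Nonempty weighted igraph graph.
#' @param partition Partition from [detect_communities()].
#' @return Named numeric vector of length 9. Density and centralization are
#'   `NA` for single-node graphs.
#' @export
compute_global_structural <- function(net, partition) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  d_inv <- shortest_paths_matrix(net, "inverse-weight")
  fin_inv <- d_inv[upper.tri(d_inv)]
  trans <- igraph::transitivity(net, type = "global")
  # diameter: hop distances within the largest connected component
  comp <- igraph::components(net)
  giant <- igraph::V(net)$name[comp$membership == which.max(comp$csize)]
  d_hop_g <- shortest_paths_matrix(
    igraph::induced_subgraph(net, giant), "hop"
  )
  c(
    order = n,
    size = m,
    n_ordered_pairs = n * (n - 1),
    density = if (n < 2) NA_real_ else m / (n * (n - 1) / 2),
    diameter = if (n < 2) NA_real_ else max(d_hop_g),
    geodesic_distance = mean_finite(fin_inv),
    transitivity = if (is.nan(trans)) NA_real_ else trans,
    centralization = if (n < 2) NA_real_ else sum(max(deg) - deg) / (n - 1),
    n_subcommunities = partition$n_communities
  )
}

#' Global nodal features
#'
#' Four features describing a node's position in the whole weekly network:
#' normalized degree centrality `deg/(n-1)`; closeness centrality
#' `(n-1) / sum of inverse-weight distances` to reachable nodes; normalized
#' betweenness centrality (fraction of shortest paths between other node
#' pairs passing through the node); and community percent size, the size of
#' the node's subcommunity as a fraction of the order.
#'
#' @param net Weekly network.
#' @param node Vertex name.
#' @param partition Partition from [detect_communities()].
#' @param dist Optional precomputed inverse-weight distance matrix.
#' @param betweenness_weights Distance scheme for betweenness geodesics.
#' @return Named numeric vector of length 5: the four features plus the raw
#'   `community_size` count as an auxiliary value.
#' @export
compute_global_nodal <- function(net, node, partition, dist = NULL,
                                 betweenness_weights = c("inverse-weight", "hop"),
                                 btw_all = NULL) {
  betweenness_weights <- match.arg(betweenness_weights)
  node <- as.character(node)
  n <- igraph::vcount(net)
  if (is.null(dist)) dist <- shortest_paths_matrix(net, "inverse-weight")
  drow <- dist[node, setdiff(colnames(dist), node)]
  drow <- drow[is.finite(drow)]
  if (is.null(btw_all)) {
    bw <- if (betweenness_weights == "inverse-weight") {
      1 / igraph::E(net)$weight
    } else {
      NA
    }
    btw_all <- igraph::betweenness(net, weights = bw)
  }
  btw_raw <- btw_all[node]
  n_pairs <- (n - 1) * (n - 2) / 2
  comm <- partition$membership[node]
  csize <- sum(partition$membership == comm)
  c(
    degree_centrality = unname(igraph::degree(net, node)) / (n - 1),
    closeness_centrality = if (length(drow) == 0) NA_real_ else
      (n - 1) / sum(drow),
    betweenness_centrality = if (n_pairs == 0) 0 else unname(btw_raw) / n_pairs,
    community_percent_size = csize / n,
    community_size = csize
  )
}

#' Burt effective size of an ego network
#'
#' Number of alters minus the average number of ties each alter has to the
#' other alters: `k - 2 t / k`, where `k` is the alter count and `t` the
#' number of alter--alter edges.
#'
#' @param ego_net Ego network from [extract_ego_network()].
#' @return Numeric scalar in `[1, k]`.
#' @export
effective_size <- function(ego_net) {
  k <- igraph::vcount(ego_net) - 1
  t_aa <- igraph::ecount(ego_net) - k # edges not incident to the ego
  k - 2 * t_aa / k
}

#' Burt efficiency of an ego network
#'
#' Effective size divided by the order of the ego network (ego plus alters).
#' Burt's own convention divides by the alter count instead; switch with
#' `denominator = "alters"`.
#'
#' @inheritParams effective_size
#' @param denominator `"order"` (default) or `"alters"`.
#' @return Numeric scalar.
#' @export
ego_efficiency <- function(ego_net, denominator = c("order", "alters")) {
  denominator <- match.arg(denominator)
  es <- effective_size(ego_net)
  n <- igraph::vcount(ego_net)
  if (denominator == "order") es / n else es / (n - 1)
}

#' Burt constraint of an ego
#'
#' Aggregate constraint \eqn{\sum_j (p_{ij} + \sum_q p_{iq} p_{qj})^2},
#' where \eqn{p_{ij}} is the proportion of node *i*'s total tie weight
#' invested in alter *j*, and *q* ranges over contacts shared by ego and
#' *j*. Proportions are computed within the ego network, so constraint
#' measures how concentrated the ego's investment is on interconnected
#' alters. A single-alter ego has constraint 1.
#'
#' @inheritParams effective_size
#' @return Positive numeric scalar.
#' @export
burt_constraint <- function(ego_net) {
  ego <- ego_net$ego
  el <- igraph::as_data_frame(ego_net, what = "edges")
  w <- stats::setNames(c(el$weight, el$weight),
                       c(paste0(el$from, "\r", el$to),
                         paste0(el$to, "\r", el$from)))
  s <- igraph::strength(ego_net, weights = igraph::E(ego_net)$weight)
  adj <- split(c(el$to, el$from), c(el$from, el$to))
  alters <- adj[[ego]]
  p_i <- stats::setNames(w[paste0(ego, "\r", alters)] / s[ego], alters)
  total <- 0
  for (j in alters) {
    q <- intersect(alters, adj[[j]]) # shared contacts of ego and j
    indirect <- if (length(q) > 0) {
      sum(p_i[q] * w[paste0(q, "\r", j)] / s[q])
    } else {
      0
    }
    total <- total + (p_i[j] + indirect)^2
  }
  unname(total)
}

#' Two-step reach efficiency
#'
#' Fraction of the other nodes of the whole weekly network that lie within
#' two hops of the ego, divided by the order of the ego network. The double
#' normalization penalizes egos whose reach comes from a large personal
#' network rather than from well-placed ties. `denominator = "alters"`
#' divides by the alter count instead of the ego-network order.
#'
#' @param net Whole weekly network.
#' @param ego Vertex name.
#' @param denominator `"order"` or `"alters"` of the ego network.
#' @return Numeric scalar in (0, 1\].
#' @export
reach_efficiency <- function(net, ego, denominator = c("order", "alters")) {
  denominator <- match.arg(denominator)
  ego <- as.character(ego)
  n <- igraph::vcount(net)
  within2 <- igraph::ego(net, order = 2, nodes = ego)[[1]]
  reach <- (length(within2) - 1) / (n - 1) # exclude the ego itself
  k <- length(igraph::neighbors(net, ego))
  reach / (if (denominator == "order") k + 1 else k)
}

#' Average dyadic redundancy
#'
#' Mean over alters of the number of the ego's *other* alters that the
#' alter is also tied to — the alter's degree within the ego network minus
#' its tie to the ego.
#'
#' @inheritParams effective_size
#' @return Non-negative numeric scalar.
#' @export
avg_dyadic_redundancy <- function(ego_net) {
  ego <- ego_net$ego
  alters <- setdiff(igraph::V(ego_net)$name, ego)
  mean(igraph::degree(ego_net, v = alters) - 1)
}

#' Average ego--alter neighbourhood similarity
#'
#' Mean over alters of the number of neighbours shared by the ego and the
#' alter, computed in the whole weekly network.
#'
#' @param net Whole weekly network.
#' @param ego Vertex name.
#' @param adj_list Optional precomputed neighbour list (named list of
#'   vertex-name vectors) to avoid repeated lookups when iterating a whole
#'   network.
#' @return Non-negative numeric scalar.
#' @export
avg_similarity <- function(net, ego, adj_list = NULL) {
  ego <- as.character(ego)
  if (is.null(adj_list)) adj_list <- name_adj_list(net)
  nb_ego <- adj_list[[ego]]
  mean(vapply(nb_ego, function(j) {
    length(intersect(nb_ego, adj_list[[j]]))
  }, numeric(1)))
}

#' Egocentric feature block
#'
#' The 13 egocentric features for one participant-week: Burt effective
#' size, efficiency and constraint, two-step reach efficiency, average
#' dyadic redundancy, average similarity, the ego's betweenness over
#' alter--alter pairs within the ego network, and the global structural
#' formulas (size, ordered pairs, density, geodesic distance, transitivity,
#' degree centralization) applied to the ego network. Degenerate
#' denominators on single-edge egos (transitivity, centralization,
#' betweenness) fall back to 0 so the person-week row survives.
#'
#' @param net Whole weekly network.
#' @param ego Vertex name (must have degree >= 1 in `net`).
#' @param ego_net Optional precomputed ego network.
#' @param betweenness_weights Distance scheme for ego betweenness geodesics.
#' @param efficiency_denominator Passed to [ego_efficiency()].
#' @param reach_denominator Passed to [reach_efficiency()].
#' @param adj_list Optional precomputed neighbour list of `net`.
#' @return Named numeric vector of length 13.
#' @export
compute_ego_features <- function(net, ego, ego_net = NULL,
                                 betweenness_weights = c("inverse-weight", "hop"),
                                 efficiency_denominator = "order",
                                 reach_denominator = "order",
                                 adj_list = NULL) {
  betweenness_weights <- match.arg(betweenness_weights)
  ego <- as.character(ego)
  if (is.null(ego_net)) ego_net <- extract_ego_network(net, ego)
  if (is.null(ego_net)) stop("ego ", ego, " is not present in the network")
  n <- igraph::vcount(ego_net)
  m <- igraph::ecount(ego_net)
  k <- n - 1 # alters
  deg <- igraph::degree(ego_net)
  d_inv <- shortest_paths_matrix(ego_net, "inverse-weight")
  trans <- igraph::transitivity(ego_net, type = "global")

  bw <- if (betweenness_weights == "inverse-weight") {
    1 / igraph::E(ego_net)$weight
  } else {
    NA
  }
  alter_pairs <- k * (k - 1) / 2
  btw_ego <- if (alter_pairs == 0) 0 else
    unname(igraph::betweenness(ego_net, v = ego, weights = bw)) / alter_pairs

  c(
    avg_dyadic_redundancy = avg_dyadic_redundancy(ego_net),
    avg_similarity = avg_similarity(net, ego, adj_list = adj_list),
    betweenness_ego = btw_ego,
    centralization_ego = sum(max(deg) - deg) / (n - 1),
    constraint = burt_constraint(ego_net),
    density_ego = m / (n * (n - 1) / 2),
    effective_size = effective_size(ego_net),
    efficiency = ego_efficiency(ego_net, efficiency_denominator),
    geodesic_distance_ego = mean_finite(d_inv[upper.tri(d_inv)]),
    n_ordered_pairs_ego = n * (n - 1),
    reach_efficiency = reach_efficiency(net, ego, reach_denominator),
    size_ego = m,
    transitivity_ego = if (is.nan(trans)) 0 else trans
  )
}

#' Assemble the person-week feature matrix
#'
#' One row per (participant, week) where the participant has at least one
#' reconciled interaction that week, holding all 26 network features plus
#' the week index. Global structural columns are constant within a week;
#' the modularity partition is computed once per weekly network (fixed
#' seed) and reused for every nodal row. The auxiliary raw
#' `community_size` count is appended after the canonical columns.
#'
#' @param networks Named list of weekly networks (names = week index).
#' @param participants Optional character vector restricting the rows.
#' @param seed Community-detection seed.
#' @param betweenness_weights,efficiency_denominator,reach_denominator
#'   Convention flags, see the individual feature functions.
#' @return Data.frame with columns `participant_id`, `week`, the 26
#'   features in canonical order, and `community_size`.
#' @export
assemble_feature_matrix <- function(networks, participants = NULL, seed = 2012,
                                    betweenness_weights = "inverse-weight",
                                    efficiency_denominator = "order",
                                    reach_denominator = "order") {
  rows <- list()
  for (wname in names(networks)) {
    net <- networks[[wname]]
    if (igraph::vcount(net) == 0) next
    week <- if (!is.null(net$week_index) && !is.na(net$week_index)) {
      net$week_index
    } else {
      as.integer(wname)
    }
    part <- detect_communities(net, seed = seed)
    glob <- compute_global_structural(net, part)
    d_inv <- shortest_paths_matrix(net, "inverse-weight")
    adj_list <- name_adj_list(net)
    bw <- if (betweenness_weights == "inverse-weight") {
      1 / igraph::E(net)$weight
    } else {
      NA
    }
    btw_all <- igraph::betweenness(net, weights = bw)
    nodes <- sort(igraph::V(net)$name)
    if (!is.null(participants)) {
      nodes <- intersect(nodes, as.character(participants))
    }
    for (v in nodes) {
      nodal <- compute_global_nodal(net, v, part, dist = d_inv,
                                    betweenness_weights = betweenness_weights,
                                    btw_all = btw_all)
      ego <- compute_ego_features(
        net, v,
        betweenness_weights = betweenness_weights,
        efficiency_denominator = efficiency_denominator,
        reach_denominator = reach_denominator,
        adj_list = adj_list
      )
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = v, week = as.integer(week),
        t(glob), t(nodal[setdiff(names(nodal), "community_size")]),
        t(ego), community_size = unname(nodal["community_size"]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    stop("no participant has any reconciled interaction in any week")
  }
  out <- do.call(rbind, rows)
  out <- out[c("participant_id", "week", FEATURE_COLUMNS, "community_size")]
  out <- out[order(out$week, out$participant_id), ]
  rownames(out) <- NULL
  out
}

# -- internal -----------------------------------------------------------------

mean_finite <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

name_adj_list <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  adj <- split(c(el$to, el$from), c(el$from, el$to))
  # isolated vertices (possible in induced subgraphs) get empty entries
  for (v in setdiff(igraph::V(g)$name, names(adj))) adj[[v]] <- character(0)
  adj
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
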