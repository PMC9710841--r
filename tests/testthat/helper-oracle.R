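# Independent brute-force implementations of every network feature, used as
# oracles against the package. Everything here works on a plain symmetric
# weight matrix (0 = no edge) by exhaustive enumeration: all simple paths for
# distances/geodesics, all triplets for transitivity, all set partitions for
# modularity. Deliberately shares no code with R/.

o_nbrs <- function(W, v) which(W[v, ] > 0)

# All simple paths s -> t as integer vectors (including endpoints).
o_paths <- function(W, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (v in o_nbrs(W, last)) {
      if (!(v %in% path)) walk(c(path, v))
    }
  }
  walk(s)
  out
}

# Distances and geodesic sets under a scheme ("inv" = 1/weight, "hop" = 1).
o_shortest <- function(W, scheme = "inv") {
  n <- nrow(W)
  L <- ifelse(W > 0, if (scheme == "inv") 1 / W else 1, Inf)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  geo <- vector("list", n * n)
  dim(geo) <- c(n, n)
  for (s in 1:n) for (t in 1:n) {
    if (s >= t) next
    paths <- o_paths(W, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(p) {
      sum(L[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    d[s, t] <- d[t, s] <- min(lens)
    geo[[s, t]] <- paths[lens <= min(lens) + 1e-9]
  }
  list(d = d, geo = geo)
}

o_betweenness <- function(W, v, sp = o_shortest(W, "inv")) {
  n <- nrow(W)
  tot <- 0
  for (s in 1:n) for (t in 1:n) {
    if (s >= t || s == v || t == v) next
    g <- sp$geo[[s, t]]
    if (is.null(g)) next
    tot <- tot + mean(vapply(g, function(p) v %in% p, logical(1)))
  }
  n_pairs <- (n - 1) * (n - 2) / 2
  if (n_pairs == 0) 0 else tot / n_pairs
}

o_closeness <- function(W, v, sp = o_shortest(W, "inv")) {
  d <- sp$d[v, -v]
  d <- d[is.finite(d)]
  if (length(d) == 0) NA_real_ else (nrow(W) - 1) / sum(d)
}

o_transitivity <- function(W) {
  A <- W > 0
  n <- nrow(W)
  triples <- 0
  closed <- 0
  for (j in 1:n) {
    nb <- which(A[j, ])
    if (length(nb) < 2) next
    for (a in nb) for (b in nb) {
      if (a >= b) next
      triples <- triples + 1
      if (A[a, b]) closed <- closed + 1
    }
  }
  if (triples == 0) NA_real_ else closed / triples
}

o_components <- function(W) {
  d <- o_shortest(W, "hop")$d
  memb <- rep(NA_integer_, nrow(W))
  k <- 0
  for (v in seq_len(nrow(W))) {
    if (is.na(memb[v])) {
      k <- k + 1
      memb[is.finite(d[v, ])] <- k
    }
  }
  memb
}

o_diameter <- function(W) {
  memb <- o_components(W)
  big <- which(memb == which.max(tabulate(memb)))
  if (length(big) < 2) return(0)
  d <- o_shortest(W[big, big, drop = FALSE], "hop")$d
  max(d)
}

# Exhaustive weighted-modularity maximization over all set partitions
# (restricted growth string enumeration).
o_partitions <- function(n) {
  out <- list()
  grow <- function(s, m) {
    if (length(s) == n) {
      out[[length(out) + 1]] <<- s
      return()
    }
    for (v in seq_len(m + 1)) grow(c(s, v), max(m, v))
  }
  grow(1L, 1L)
  out
}

o_modularity <- function(W, memb) {
  m2 <- sum(W) # 2m
  k <- rowSums(W)
  same <- outer(memb, memb, "==")
  sum((W - outer(k, k) / m2) * same) / m2
}

o_best_partition <- function(W) {
  parts <- o_partitions(nrow(W))
  qs <- vapply(parts, function(p) o_modularity(W, p), numeric(1))
  best <- which.max(qs)
  list(membership = parts[[best]], q = qs[best],
       n_communities = length(unique(parts[[best]])))
}

# -- egocentric oracles -------------------------------------------------------

o_effective_size <- function(W, ego) {
  alters <- o_nbrs(W, ego)
  k <- length(alters)
  t_aa <- sum(W[alters, alters, drop = FALSE] > 0) / 2
  k - 2 * t_aa / k
}

o_constraint <- function(W, ego) {
  keep <- c(ego, o_nbrs(W, ego))
  Wr <- W[keep, keep, drop = FALSE]
  p <- Wr / rowSums(Wr)
  e <- 1 # ego is first after restriction
  alters <- which(Wr[e, ] > 0)
  tot <- 0
  for (j in alters) {
    ind <- 0
    for (q in alters) {
      if (q != j && Wr[q, j] > 0) ind <- ind + p[e, q] * p[q, j]
    }
    tot <- tot + (p[e, j] + ind)^2
  }
  tot
}

o_reach_efficiency <- function(W, ego) {
  A <- W > 0
  two <- (A | (A %*% A) > 0)
  reached <- sum(two[ego, -ego] > 0)
  k <- length(o_nbrs(W, ego))
  (reached / (nrow(W) - 1)) / (k + 1)
}

o_redundancy <- function(W, ego) {
  alters <- o_nbrs(W, ego)
  mean(vapply(alters, function(j) {
    length(intersect(o_nbrs(W, j), setdiff(alters, j)))
  }, numeric(1)))
}

o_similarity <- function(W, ego) {
  alters <- o_nbrs(W, ego)
  mean(vapply(alters, function(j) {
    length(intersect(o_nbrs(W, j), alters))
  }, numeric(1)))
}

o_betweenness_ego <- function(W, ego) {
  keep <- c(ego, o_nbrs(W, ego))
  Wr <- W[keep, keep, drop = FALSE]
  k <- length(keep) - 1
  if (k < 2) return(0)
  sp <- o_shortest(Wr, "inv")
  tot <- 0
  for (s in 2:(k + 1)) for (t in 2:(k + 1)) {
    if (s >= t) next
    g <- sp$geo[[s, t]]
    tot <- tot + mean(vapply(g, function(p) 1 %in% p, logical(1)))
  }
  tot / (k * (k - 1) / 2)
}

# Full 26-feature oracle row for one node (matrix indices; names must match
# the package's canonical feature columns).
o_feature_row <- function(W, v, part = o_best_partition(W)) {
  n <- nrow(W)
  deg <- rowSums(W > 0)
  sp_inv <- o_shortest(W, "inv")
  fin <- sp_inv$d[upper.tri(sp_inv$d)]
  keep <- c(v, o_nbrs(W, v))
  Wr <- W[keep, keep, drop = FALSE]
  nr <- nrow(Wr)
  deg_r <- rowSums(Wr > 0)
  sp_r <- o_shortest(Wr, "inv")
  fin_r <- sp_r$d[upper.tri(sp_r$d)]
  tr <- o_transitivity(W)
  tr_r <- o_transitivity(Wr)
  c(
    order = n,
    size = sum(W > 0) / 2,
    n_ordered_pairs = n * (n - 1),
    density = (sum(W > 0) / 2) / (n * (n - 1) / 2),
    diameter = o_diameter(W),
    geodesic_distance = mean(fin[is.finite(fin)]),
    transitivity = if (is.na(tr)) NA_real_ else tr,
    centralization = sum(max(deg) - deg) / (n - 1),
    n_subcommunities = part$n_communities,
    degree_centrality = unname(deg[v]) / (n - 1),
    closeness_centrality = o_closeness(W, v, sp_inv),
    betweenness_centrality = o_betweenness(W, v, sp_inv),
    community_percent_size = sum(part$membership == part$membership[v]) / n,
    avg_dyadic_redundancy = o_redundancy(W, v),
    avg_similarity = o_similarity(W, v),
    betweenness_ego = o_betweenness_ego(W, v),
    centralization_ego = sum(max(deg_r) - deg_r) / (nr - 1),
    constraint = o_constraint(W, v),
    density_ego = (sum(Wr > 0) / 2) / (nr * (nr - 1) / 2),
    effective_size = o_effective_size(W, v),
    efficiency = o_effective_size(W, v) / nr,
    geodesic_distance_ego = mean(fin_r[is.finite(fin_r)]),
    n_ordered_pairs_ego = nr * (nr - 1),
    reach_efficiency = o_reach_efficiency(W, v),
    size_ego = sum(Wr > 0) / 2,
    transitivity_ego = if (is.na(tr_r)) 0 else tr_r
  )
}

# Direct transcription of the variability statistic for series oracles.
o_rmssd <- function(x) {
  N <- length(x)
  acc <- 0
  for (i in 1:(N - 1)) acc <- acc + (x[i] - x[i + 1])^2
  sqrt(acc / (N - 1))
}
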