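# Closed-form values evaluated by hand from the operational definitions.

test_that("shortest paths honour the two length schemes", {
  p3 <- g_path3()
  d_hop <- shortest_paths_matrix(p3, "hop")
  expect_equal(d_hop["a", "c"], 2)
  g <- g_from_edges("a", "b", weight = 4)
  expect_equal(shortest_paths_matrix(g, "inverse-weight")["a", "b"], 0.25)
  # heavier edges are shorter: direct weight-10 edge beats a weight-1 detour
  g2 <- g_from_edges(c("a", "a", "b"), c("b", "c", "c"), weight = c(10, 1, 1))
  expect_equal(shortest_paths_matrix(g2, "inverse-weight")["a", "b"], 0.1)
})

test_that("community detection is deterministic and finds planted structure", {
  bb <- g_barbell()
  p1 <- detect_communities(bb, seed = 2012)
  expect_equal(p1$n_communities, 2)
  expect_equal(length(unique(p1$membership[paste0("a", 1:4)])), 1)
  expect_equal(detect_communities(g_triangle())$n_communities, 1)
  p2 <- detect_communities(bb, seed = 2012)
  expect_identical(p1$membership, p2$membership)
  # larger graphs go through seeded restarted Louvain; still deterministic
  set.seed(99)
  rw <- random_weighted_graph(12, p = 0.4)
  q1 <- detect_communities(rw$g, seed = 7, n_exact = 4)
  q2 <- detect_communities(rw$g, seed = 7, n_exact = 4)
  expect_identical(q1$membership, q2$membership)
})

test_that("global structural features match hand-evaluated small cases", {
  tri <- g_triangle()
  gs <- compute_global_structural(tri, detect_communities(tri))
  expect_equal(unname(gs[c("density", "transitivity", "centralization",
                           "diameter", "geodesic_distance")]),
               c(1, 1, 0, 1, 1))
  p3 <- g_path3()
  gs <- compute_global_structural(p3, detect_communities(p3))
  expect_equal(unname(gs["density"]), 2 / 3)
  expect_equal(unname(gs["transitivity"]), 0) # one open triple, none closed
  expect_equal(unname(gs["centralization"]), 1) # ((2-1)+(2-1))/2
  star <- g_star(4)
  gs <- compute_global_structural(star, detect_communities(star))
  expect_equal(unname(gs["centralization"]), 3) # 4*(4-1)/4
  expect_equal(unname(gs["transitivity"]), 0)
  expect_equal(unname(gs[c("order", "size", "n_ordered_pairs")]), c(5, 4, 20))
})

test_that("global nodal features match hand-evaluated small cases", {
  p3 <- g_path3()
  part <- detect_communities(p3)
  mid <- compute_global_nodal(p3, "b", part)
  expect_equal(unname(mid["betweenness_centrality"]), 1)
  expect_equal(unname(mid["closeness_centrality"]), 1) # 2/2
  expect_equal(unname(mid["degree_centrality"]), 1)
  end <- compute_global_nodal(p3, "a", part)
  expect_equal(unname(end["betweenness_centrality"]), 0)
  expect_equal(unname(end["closeness_centrality"]), 2 / 3)
  expect_equal(unname(mid["community_percent_size"]), 1)
})

test_that("Burt measures match their closed forms on stars and triangles", {
  for (k in 2:5) {
    hub <- extract_ego_network(g_star(k), "h")
    expect_equal(effective_size(hub), k)
    expect_equal(ego_efficiency(hub), k / (k + 1))
    expect_equal(ego_efficiency(hub, "alters"), 1)
    expect_equal(burt_constraint(hub), 1 / k)
  }
  tri_ego <- extract_ego_network(g_triangle(), "a")
  expect_equal(effective_size(tri_ego), 1)
  expect_equal(ego_efficiency(tri_ego), 1 / 3)
  expect_equal(burt_constraint(tri_ego), 1.125)
  single <- extract_ego_network(g_path3(), "a")
  expect_equal(effective_size(single), 1)
  expect_equal(ego_efficiency(single), 1 / 2)
  expect_equal(burt_constraint(single), 1)
})

test_that("weighted constraint agrees with igraph on whole-component egos", {
  # hub ego networks cover the whole graph, so igraph's whole-graph Burt
  # constraint is directly comparable
  set.seed(7)
  g <- g_from_edges(c("h", "h", "h", "a", "b"), c("a", "b", "c", "b", "c"),
                    weight = c(3, 1, 5, 2, 4))
  eh <- extract_ego_network(g, "h")
  expect_equal(burt_constraint(eh),
               unname(igraph::constraint(g, "h", weights = igraph::E(g)$weight)))
})

test_that("reach efficiency, redundancy and similarity match small cases", {
  star <- g_star(4)
  expect_equal(reach_efficiency(star, "h"), 1 / 5)
  expect_equal(reach_efficiency(star, "a"), 1 / 2)
  expect_equal(reach_efficiency(g_from_edges("a", "b"), "a"), 1 / 2)
  expect_equal(avg_dyadic_redundancy(extract_ego_network(star, "h")), 0)
  expect_equal(avg_dyadic_redundancy(extract_ego_network(g_triangle(), "a")), 1)
  # hub plus one alter-alter edge among three alters
  g <- g_from_edges(c("h", "h", "h", "a"), c("a", "b", "c", "b"))
  expect_equal(avg_dyadic_redundancy(extract_ego_network(g, "h")), 2 / 3)
  expect_equal(avg_similarity(star, "h"), 0)
  expect_equal(avg_similarity(g_triangle(), "a"), 1)
})

test_that("ego feature block matches hand-evaluated star and triangle values", {
  star <- g_star(4)
  ef <- compute_ego_features(star, "h")
  expect_equal(unname(ef["density_ego"]), 0.4)
  expect_equal(unname(ef["betweenness_ego"]), 1)
  expect_equal(unname(ef["transitivity_ego"]), 0)
  expect_equal(unname(ef["size_ego"]), 4)
  expect_equal(unname(ef["n_ordered_pairs_ego"]), 20)
  tri <- g_triangle()
  ef <- compute_ego_features(tri, "a")
  expect_equal(unname(ef["density_ego"]), 1)
  expect_equal(unname(ef["betweenness_ego"]), 0)
  # single-edge ego: degenerate denominators fall back to 0
  ef <- compute_ego_features(g_from_edges("a", "b"), "a")
  expect_equal(unname(ef["transitivity_ego"]), 0)
  expect_equal(unname(ef["centralization_ego"]), 0)
})

test_that("all 26 features match brute-force enumeration on random graphs", {
  # fast spot check; the full 200-graph suite runs in the acceptance tests
  set.seed(1234)
  for (i in 1:20) {
    rw <- random_weighted_graph(sample(3:7, 1))
    part <- o_best_partition(rw$W)
    fm <- assemble_feature_matrix(stats::setNames(list(rw$g), "1"))
    for (v in rownames(rw$W)) {
      got <- unlist(fm[fm$participant_id == v, feature_columns()])
      want <- o_feature_row(rw$W, which(rownames(rw$W) == v), part)
      expect_equal(got, want[names(got)], tolerance = 1e-9)
    }
  }
})

test_that("proportion-based features ignore global weight rescaling", {
  set.seed(55)
  rw <- random_weighted_graph(7)
  g2 <- rw$g
  igraph::E(g2)$weight <- igraph::E(g2)$weight * 13
  inv <- c("density", "transitivity", "centralization", "degree_centrality",
           "constraint", "effective_size", "efficiency", "density_ego",
           "reach_efficiency", "avg_similarity", "avg_dyadic_redundancy",
           "betweenness_centrality", "betweenness_ego")
  f1 <- assemble_feature_matrix(stats::setNames(list(rw$g), "1"))
  f2 <- assemble_feature_matrix(stats::setNames(list(g2), "1"))
  expect_equal(f1[inv], f2[inv], tolerance = 1e-12)
})

test_that("relabelling nodes permutes rows but changes no feature value", {
  set.seed(66)
  rw <- random_weighted_graph(6)
  perm <- sample(igraph::vcount(rw$g))
  g2 <- igraph::permute(rw$g, perm)
  f1 <- assemble_feature_matrix(stats::setNames(list(rw$g), "1"))
  f2 <- assemble_feature_matrix(stats::setNames(list(g2), "1"))
  f2 <- f2[match(f1$participant_id, f2$participant_id), ]
  rownames(f2) <- NULL
  expect_equal(f2, f1)
})

test_that("feature matrix has the contracted shape and scope", {
  cfg <- small_config(seed = 41, n_participants = 6)
  co <- simulate_cohort(cfg)
  fm <- assemble_feature_matrix(co$networks)
  expect_equal(names(fm),
               c("participant_id", "week", feature_columns(), "community_size"))
  # global structural columns constant within each week
  for (w in unique(fm$week)) {
    sub <- fm[fm$week == w, c("order", "size", "density", "diameter",
                              "n_subcommunities")]
    expect_true(all(vapply(sub, function(x) length(unique(x)) == 1,
                           logical(1))))
  }
  # participants absent from a week's network get no row
  net1 <- co$networks[["1"]]
  expect_setequal(fm$participant_id[fm$week == 1], igraph::V(net1)$name)
})
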