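complete_graph <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0; a
}

star_graph <- function(n) {
  a <- matrix(0, n, n); a[1, 2:n] <- 1; a[2:n, 1] <- 1; a
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

test_that("clustering coefficient on canonical graphs", {
  expect_equal(nodal_clustering(complete_graph(4)), rep(1, 4))
  expect_equal(nodal_clustering(star_graph(6)), rep(0, 6))
})

test_that("shortest-path metrics on canonical graphs", {
  k5 <- shortest_path_metrics(complete_graph(5))
  expect_equal(k5$L_p, 1)
  expect_equal(k5$E_global, 1)
  expect_equal(k5$nodal_efficiency, rep(1, 5))
  # path on 4 nodes: distance multiset {1,1,1,2,2,3}
  p4 <- shortest_path_metrics(path_graph(4))
  expect_equal(p4$L_p, 10 / 6)
  expect_equal(p4$E_global, 13 / 18)
  # two disconnected triangles: 2 reachable neighbours at distance 1, of 5
  two_k3 <- matrix(0, 6, 6)
  two_k3[1:3, 1:3] <- 1; two_k3[4:6, 4:6] <- 1; diag(two_k3) <- 0
  expect_equal(shortest_path_metrics(two_k3)$nodal_efficiency, rep(2 / 5, 6))
  # edgeless graph: sentinel path length, zero efficiency
  empty <- matrix(0, 4, 4)
  expect_true(is.na(shortest_path_metrics(empty)$L_p))
  expect_equal(shortest_path_metrics(empty)$E_global, 0)
})

test_that("betweenness on canonical graphs", {
  expect_equal(node_betweenness(path_graph(3)), c(0, 1, 0))
  # 4-cycle: each opposite pair has two equal shortest paths
  c4 <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; c4[i, j] <- c4[j, i] <- 1 }
  expect_equal(node_betweenness(c4), rep(0.5, 4))
})

test_that("local efficiency on canonical graphs", {
  expect_equal(nodal_local_efficiency(complete_graph(4)), rep(1, 4))
  expect_equal(nodal_local_efficiency(star_graph(6))[1], 0)
})

test_that("all nodal metrics match brute-force oracles on random graphs", {
  set.seed(99)
  cases <- data.frame(n = sample(5:12, 50, replace = TRUE),
                      p = stats::runif(50, 0.15, 0.7),
                      seed = 1:50)
  for (k in seq_len(nrow(cases))) {
    a <- random_adjacency(cases$n[k], cases$p[k], cases$seed[k])
    sp <- shortest_path_metrics(a)
    expect_equal(nodal_clustering(a), oracle_clustering(a), tolerance = 1e-12)
    expect_equal(node_betweenness(a), oracle_betweenness(a), tolerance = 1e-9)
    expect_equal(sp$nodal_efficiency, oracle_nodal_efficiency(a), tolerance = 1e-12)
    expect_equal(sp$nodal_shortest_path, oracle_nodal_shortest_path(a),
                 tolerance = 1e-12)
    expect_equal(nodal_local_efficiency(a), oracle_local_efficiency(a),
                 tolerance = 1e-12)
    expect_equal(sp$E_global, oracle_global_efficiency(a), tolerance = 1e-12)
    d <- oracle_distances(a); diag(d) <- NA
    if (any(is.finite(d), na.rm = TRUE))
      expect_equal(sp$L_p, mean(d[is.finite(d)]), tolerance = 1e-12)
  }
})

test_that("bounded metrics respect their ranges on many random graphs", {
  set.seed(17)
  for (k in 1:200) {
    a <- random_adjacency(sample(4:15, 1), stats::runif(1, 0.05, 0.9), 1000 + k)
    cc <- nodal_clustering(a)
    sp <- shortest_path_metrics(a)
    le <- nodal_local_efficiency(a)
    deg <- rowSums(a)
    expect_true(all(cc >= 0 & cc <= 1))
    expect_true(all(sp$nodal_efficiency >= 0 & sp$nodal_efficiency <= 1))
    expect_true(all(le >= 0 & le <= 1))
    expect_true(all(deg >= 0 & deg <= nrow(a) - 1))
    expect_equal(sum(deg), sum(a))              # degree sum = 2 |E|
    expect_true(sp$E_global >= 0 && sp$E_global <= 1)
    if (sum(a) > 0) expect_gte(sp$L_p, 1)
  }
})

test_that("modularity formula and greedy optimisation", {
  # two disconnected K4s under the component partition: Q = 1/2
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1; a[5:8, 5:8] <- 1; diag(a) <- 0
  expect_equal(modularity_q(a, rep(1:2, each = 4))$Q, 0.5)
  # everything in one module: Q = 0
  expect_equal(modularity_q(a, rep(1, 8))$Q, 0)
  # greedy finds the component split here
  g <- modularity_greedy(a)
  expect_equal(g$Q, 0.5)
  expect_equal(length(unique(g$membership)), 2)
  # bookkeeping invariants: sum(l) <= L, sum(d) = 2L
  expect_lte(sum(g$l), g$L)
  expect_equal(sum(g$d), 2 * g$L)
  expect_error(modularity_greedy(matrix(0, 4, 4)), "edgeless")
})

test_that("greedy Q is bounded by the exhaustive maximum and close on average", {
  set.seed(31)
  ratio <- c()
  for (k in 1:50) {
    a <- random_adjacency(sample(5:8, 1), stats::runif(1, 0.25, 0.7), 2000 + k)
    if (sum(a) == 0) next
    qg <- modularity_greedy(a)$Q
    qx <- oracle_max_modularity(a)
    expect_lte(qg, qx + 1e-12)
    if (qx > 0) ratio <- c(ratio, qg / qx)
  }
  expect_gte(mean(ratio), 0.9)
})

test_that("agreement with independent igraph modularity on the same partition", {
  set.seed(13)
  a <- random_adjacency(12, 0.3, 77)
  part <- modularity_greedy(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  expect_equal(part$Q, igraph::modularity(g, part$membership), tolerance = 1e-12)
})

test_that("null ensemble preserves degree sequences and is seeded", {
  a <- random_adjacency(20, 0.3, 4)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  for (r in 1:10) {
    set.seed(100 + r)
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    expect_equal(sort(igraph::degree(gr)), sort(rowSums(a)), ignore_attr = TRUE)
  }
  e1 <- null_ensemble(a, n_random = 5, seed = 3)
  e2 <- null_ensemble(a, n_random = 5, seed = 3)
  expect_identical(e1, e2)
})

test_that("small-world normalisation: self-null consistency and sigma > 1 on lattices", {
  # a graph rewired from its own degree family sits at gamma ~ 1, lambda ~ 1
  a <- random_adjacency(24, 0.25, 6)
  ens <- null_ensemble(a, n_random = 60, seed = 2)
  cp <- mean(nodal_clustering(a))
  lp <- shortest_path_metrics(a)$L_p
  sw <- small_world_normalize(cp, lp, ens)
  se_c <- stats::sd(ens$Cp)   # dispersion of a single draw from the family
  se_l <- stats::sd(ens$Lp)
  expect_lt(abs(cp - ens$mean_Cp), 3 * se_c + 1e-9)
  expect_lt(abs(lp - ens$mean_Lp), 3 * se_l + 1e-9)
  expect_equal(sw[["gamma"]], cp / ens$mean_Cp)
  expect_equal(sw[["sigma"]], sw[["gamma"]] / sw[["lambda"]])
  # ring lattice with shortcuts is small-world: sigma > 1 across seeds
  for (s in 1:10) {
    ring <- make_ring_with_shortcuts(30, 6, s)
    ens_r <- null_ensemble(ring, n_random = 20, seed = s)
    sw_r <- small_world_normalize(mean(nodal_clustering(ring)),
                                  shortest_path_metrics(ring)$L_p, ens_r)
    expect_gt(sw_r[["sigma"]], 1)
  }
})

test_that("AUC over the grid is the plain 49-value sum", {
  expect_equal(metric_auc(rep(0.3, 49)), 14.7)
  expect_equal(metric_auc(rep(0, 49)), 0)
  expect_equal(metric_auc(1:49), 1225)
  expect_error(metric_auc(c(1, NA, 3)), "non-finite")
  expect_error(metric_auc(1:48, n_expected = 49), "expected 49")
})

test_that("hub selection takes ceil(5%) with deterministic index tie-break", {
  expect_length(identify_hubs(stats::runif(90)), 5)
  expect_equal(identify_hubs(c(3, 9, 1, 5, 2, 0, 4, 6, 8, 7, 3, 1, 2, 5, 4,
                               0, 1, 2, 3, 4)), 2)  # N=20 -> single hub
  w <- c(5, 3, 3, 3, 1, 1)   # ties at the cutoff
  expect_equal(identify_hubs(w, prop = 0.5), c(1, 2, 3))
  expect_identical(identify_hubs(w, prop = 0.5), identify_hubs(w, prop = 0.5))
})

test_that("E_global never decreases as the network densifies", {
  set.seed(44)
  conn <- compute_connectivity(matrix(rnorm(150 * 12), 150))
  graphs <- suppressWarnings(threshold_series(conn, sparsity_grid()))
  eg <- vapply(graphs, function(a) shortest_path_metrics(a)$E_global, numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("subject_metrics aggregates per-threshold values into AUC features", {
  set.seed(10)
  spec <- cohort_spec(n_group_pos = 2, n_group_neg = 2, n_roi = 20,
                      n_timepoints = 100, seed = 10)
  conn <- compute_connectivity(
    simulate_subject(build_population_covariance(spec, "neg"), 100, 0.3, 1))
  grid <- sparsity_grid(0.2, 0.5, 0.05)
  sm <- subject_metrics(conn, grid, n_random = 10, seed = 2)
  expect_equal(dim(sm$global), c(length(grid), 7))
  expect_equal(dim(sm$auc_nodal), c(20, 6))
  expect_equal(unname(sm$auc_global["Cp"]), sum(sm$global[, "Cp"]))
  expect_equal(sm$auc_nodal[3, "degree"], sum(sm$nodal[3, "degree", ]))
  # deterministic given seed
  sm2 <- subject_metrics(conn, grid, n_random = 10, seed = 2)
  expect_identical(sm, sm2)
})
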