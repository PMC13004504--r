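# Swap a known edge pair through the deterministic cores to pin down the
# committed/rejected behaviour of each algorithm, then exercise the random
# attempt operators and the controller on synthetic networks.

test_that("assortativity swap pairs high with high and rejects ties", {
  # degrees (4,1) on one edge and (3,2) on the other: product sum 10 -> 14
  el <- cbind(c(1, 1, 1, 1, 3, 3, 3, 4),
              c(2, 5, 6, 7, 4, 5, 6, 7))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  deg <- igraph::degree(g)
  expect_equal(deg[c(1, 2, 3, 4)], c(4, 1, 3, 2), ignore_attr = TRUE)
  out <- netrewire:::eval_assortativity_swap(g, 1, 2, 3, 4)
  expect_true(out$committed)
  expect_equal(out$detail$jk_before, 10)
  expect_equal(out$detail$jk_after, 14)
  expect_equal(sort(igraph::degree(out$network)), sort(deg), ignore_attr = TRUE)

  # already optimally paired: (4,3) and (2,1) -> no alternative improves
  el2 <- cbind(c(1, 1, 1, 1, 2, 2, 3, 3),
               c(2, 5, 6, 7, 6, 7, 4, 5))
  g2 <- igraph::graph_from_edgelist(el2, directed = FALSE)
  expect_equal(igraph::degree(g2)[1:4], c(4, 3, 2, 1), ignore_attr = TRUE)
  out2 <- netrewire:::eval_assortativity_swap(g2, 1, 2, 3, 4)
  expect_false(out2$committed)
  expect_equal(out2$reason, "already-optimal")

  # all-equal degrees: ties are never an improvement
  k4 <- toy_graph("complete4")
  out3 <- netrewire:::eval_assortativity_swap(k4, 1, 2, 3, 4)
  expect_equal(out3$reason, "already-optimal")
})

test_that("star graphs admit no assortativity swap and keep r = -1", {
  g <- toy_graph("star4")
  set.seed(1)
  for (i in 1:25) {
    out <- attempt_assortativity_swap(g)
    expect_false(out$committed)
    expect_equal(out$reason, "degenerate-selection") # any two edges share the hub
  }
  expect_equal(degree_assortativity(g), -1)
})

test_that("clustering rewire on the chorded 6-cycle closes two triangles", {
  g <- toy_graph("cycle6_chord")
  expect_equal(mean_local_clustering(g), 0)
  out <- netrewire:::eval_clustering_rewire(g, 4, 3, 5, 2, 6)
  expect_true(out$committed)
  expect_equal(out$detail$cbar_after, 7 / 9)
  expect_equal(mean_local_clustering(out$network), 7 / 9)
  expect_equal(sort(igraph::degree(out$network)), sort(igraph::degree(g)))
})

test_that("clustering rewire rejects disconnection, duplicates and losses", {
  # breaking both ends of the full 5-path strands a triangle plus an edge
  out <- netrewire:::eval_clustering_rewire(toy_graph("path5"), 3, 2, 4, 1, 5)
  expect_equal(out$reason, "would-disconnect")
  # on the 5-cycle the degree-repair edge (p,q) already exists
  out2 <- netrewire:::eval_clustering_rewire(toy_graph("cycle5"), 3, 2, 4, 1, 5)
  expect_equal(out2$reason, "duplicate-edge")
  # no 5-node path from a star centre
  set.seed(2)
  for (i in 1:10) {
    out3 <- attempt_clustering_rewire(toy_graph("star4"))
    expect_equal(out3$reason, "no-valid-path")
  }
})

test_that("geodesic rewire commits only on strict decrease of the mean", {
  # neighbours on opposite arcs of a 6-cycle: result is again a 6-cycle
  out <- netrewire:::eval_geodesic_rewire(toy_graph("cycle6"), 1, 4, 2, 5)
  expect_equal(out$reason, "no-improvement")
  # shortcutting the most distant pair of two bridged triangles commits
  g <- toy_graph("bridged_triangles")
  l0 <- geodesic_stats(g)$mean
  out2 <- netrewire:::eval_geodesic_rewire(g, 1, 7, 2, 6)
  expect_true(out2$committed)
  D <- oracle_apsp(out2$network)
  expect_equal(out2$detail$geodesic_after, mean(D[upper.tri(D)]))
  expect_lt(out2$detail$geodesic_after, l0)
  # stranding the two ends of a 5-path disconnects
  out3 <- netrewire:::eval_geodesic_rewire(toy_graph("path5"), 1, 5, 2, 4)
  expect_equal(out3$reason, "would-disconnect")
  # duplicate shortcut edge
  out4 <- netrewire:::eval_geodesic_rewire(toy_graph("paw"), 1, 2, 3, 3)
  expect_equal(out4$reason, "degenerate-selection")
})

test_that("every attempt preserves the degree multiset, simplicity and connectivity", {
  g <- test_network(seed = 21)
  deg0 <- sort(igraph::degree(g))
  set.seed(22)
  dist <- igraph::distances(g)
  cbar <- mean_local_clustering(g)
  for (i in 1:200) {
    alg <- c("assortativity", "clustering", "geodesic")[(i %% 3) + 1]
    out <- switch(alg,
      assortativity = attempt_assortativity_swap(g),
      clustering = attempt_clustering_rewire(g, cbar = cbar),
      geodesic = attempt_geodesic_rewire(g, dist = dist)
    )
    expect_equal(out$committed, out$reason == "committed")
    g <- out$network
    if (out$committed) {
      if (alg == "clustering") cbar <- out$detail$cbar_after
      if (alg == "geodesic") dist <- out$detail$distances else dist <- igraph::distances(g)
      if (alg != "clustering") cbar <- mean_local_clustering(g)
    }
    expect_equal(sort(igraph::degree(g)), deg0)
    expect_false(igraph::any_loop(g) || igraph::any_multiple(g))
    expect_true(igraph::is_connected(g))
  }
})

test_that("rewiring configs derive the documented defaults and reject bad input", {
  cfg <- rewiring_config("assortativity", edges = 412)
  expect_equal(cfg$window, ceiling(0.2 * 412))
  expect_equal(cfg$max_attempts, 4120)
  expect_equal(cfg$convergence, 0.9)
  cfg2 <- rewiring_config("geodesic", edges = 412)
  expect_equal(cfg2$window, ceiling(0.1 * 412))
  expect_equal(cfg2$max_attempts, 412)
  expect_error(rewiring_config("clustering", edges = 10, window = 0), "window")
  expect_error(rewiring_config("clustering", edges = 10, convergence = 1), "convergence")
  expect_error(rewiring_config("clustering", edges = 10, convergence = 0), "convergence")
})

test_that("a run with no possible swap stops after one window with two snapshots", {
  g <- toy_graph("complete4")
  run <- run_rewiring(g, rewiring_config("assortativity", edges = 6, seed = 5))
  traj <- run$trajectory
  expect_equal(nrow(traj), 2)
  expect_equal(traj$attempt, c(0, ceiling(0.2 * 6)))
  expect_equal(traj$successes, c(0, 0))
  expect_equal(run$termination, "converged")
})

test_that("trajectories are monotone in the target, degree-invariant and reproducible", {
  g <- test_network(n = 100, k = 5, seed = 31)
  m <- igraph::ecount(g)
  for (alg in c("assortativity", "clustering", "geodesic")) {
    cfg <- rewiring_config(alg, edges = m, seed = 77)
    run <- run_rewiring(g, cfg)
    traj <- run$trajectory
    expect_lte(max(traj$attempt), cfg$max_attempts)
    expect_equal(traj$attempt[1], 0)
    expect_true(all(diff(traj$attempt) > 0))
    expect_true(all(diff(traj$successes) >= 0))
    # degree sequence never moves
    expect_equal(unique(traj$degree_mean), traj$degree_mean[1])
    expect_equal(unique(traj$degree_gini), traj$degree_gini[1])
    expect_equal(sort(igraph::degree(run$network)), sort(igraph::degree(g)))
    # target property monotone in the required direction
    target <- switch(alg, assortativity = traj$assortativity,
                     clustering = traj$local_clustering_mean,
                     geodesic = traj$geodesic_mean)
    if (alg == "geodesic") {
      expect_true(all(diff(target) <= 0))
    } else {
      expect_true(all(diff(target) >= -1e-12))
    }
    # identical seed => identical trajectory
    rerun <- run_rewiring(g, cfg)
    expect_equal(rerun$trajectory, traj)
    expect_equal(edge_set_of(rerun$network), edge_set_of(run$network))
  }
})

test_that("snapshot interval follows the window and a terminal snapshot exists", {
  g <- test_network(n = 80, k = 4, seed = 41)
  cfg <- rewiring_config("assortativity", edges = igraph::ecount(g),
                         window = 25, max_attempts = 130, seed = 9)
  run <- run_rewiring(g, cfg)
  traj <- run$trajectory
  inner <- traj$attempt[traj$attempt > 0 & traj$attempt < max(traj$attempt)]
  expect_true(all(inner %% 25 == 0))
  final <- max(traj$attempt)
  expect_true(final == 130 || final %% 25 == 0)
})
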