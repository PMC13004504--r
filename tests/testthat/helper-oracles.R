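# Independent brute-force oracles for the structural metrics. These work
# from the dense adjacency matrix with elementary definitions only, so they
# share no code path with the package implementations they check.

adj_of <- function(g) igraph::as_adjacency_matrix(g, sparse = FALSE)

# Pearson correlation of endpoint degrees over both orientations of every
# edge (the definitional form of degree assortativity). NA when the
# endpoint degrees have zero variance.
oracle_assortativity <- function(g) {
  A <- adj_of(g)
  deg <- rowSums(A)
  e <- igraph::as_edgelist(g, names = FALSE)
  x <- c(deg[e[, 1]], deg[e[, 2]])
  y <- c(deg[e[, 2]], deg[e[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

oracle_local_clustering <- function(g) {
  A <- adj_of(g)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) return(0)
    sum(A[nb, nb]) / 2 / choose(d, 2)
  }, 0)
}

oracle_transitivity <- function(g) {
  A <- adj_of(g)
  tri <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(choose(rowSums(A), 2))
  if (triples == 0) 0 else 3 * tri / triples
}

# Floyd-Warshall all-pairs shortest paths (dynamic programming, no BFS).
oracle_apsp <- function(g) {
  A <- adj_of(g)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

oracle_closeness <- function(g, D = oracle_apsp(g)) {
  (nrow(D) - 1) / rowSums(D)
}

# Betweenness from shortest-path counts: nsp[s, v] (number of shortest
# s-v paths) is accumulated over nodes in order of distance from s; the
# pair dependency of v is nsp[s,v] * nsp[t,v] / nsp[s,t] whenever v lies
# on a shortest s-t path. Endpoints excluded; normalized by (n-1)(n-2)/2.
oracle_betweenness <- function(g, D = oracle_apsp(g)) {
  A <- adj_of(g)
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    nsp[s, s] <- 1
    for (v in order(D[s, ])) {
      if (v == s) next
      pred <- which(A[v, ] == 1 & D[s, ] == D[s, v] - 1)
      nsp[s, v] <- sum(nsp[s, pred])
    }
  }
  b <- rep(0, n)
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], "+") == D       # v lies on a shortest s-t path
    frac <- outer(nsp[, v], nsp[v, ]) / nsp          # sigma_st(v) / sigma_st
    use <- on_path & upper.tri(D)
    use[v, ] <- FALSE
    use[, v] <- FALSE
    b[v] <- sum(frac[use])
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Exhaustive simple-path enumeration (the slowest, most literal oracle);
# used on a modest sample to back the counting oracle above.
oracle_betweenness_enum <- function(g) {
  A <- adj_of(g)
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  paths_between <- function(s, t) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (nxt in which(A[last, ] == 1)) {
        if (!(nxt %in% path)) grow(c(path, nxt))
      }
    }
    grow(s)
    lens <- lengths(out)
    out[lens == min(lens)]
  }
  b <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      sp <- paths_between(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        b[v] <- b[v] + mean(vapply(sp, function(p) v %in% p, TRUE))
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

oracle_eigenvector <- function(g) {
  A <- adj_of(g)
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  v / sqrt(sum(v^2))
}

# Definitional O(n^2) Gini: normalized mean absolute pairwise difference.
oracle_gini_def <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Largest absolute disagreement between the package metrics and the
# brute-force oracles on one graph (Inf if the undefined-assortativity
# sentinel disagrees). Used for the exhaustive small-graph sweep, where
# per-metric expectations would dominate the runtime.
metric_discrepancy <- function(g) {
  D <- oracle_apsp(g)
  gs <- geodesic_stats(g)
  r_imp <- degree_assortativity(g)
  r_or <- oracle_assortativity(g)
  r_diff <- if (is.na(r_or) || is.na(r_imp)) {
    if (is.na(r_or) == is.na(r_imp)) 0 else Inf
  } else {
    abs(r_imp - r_or)
  }
  max(
    r_diff,
    max(abs(local_clustering(g) - oracle_local_clustering(g))),
    abs(transitivity_global(g) - oracle_transitivity(g)),
    abs(gs$mean - mean(D[upper.tri(D)])),
    abs(gs$diameter - max(D[upper.tri(D)])),
    max(abs(closeness_all(g) - oracle_closeness(g, D))),
    max(abs(betweenness_all(g) - oracle_betweenness(g, D))),
    max(abs(eigenvector_all(g, tol = 1e-12) - oracle_eigenvector(g)))
  )
}

expect_metrics_match_oracles <- function(g, tol = 1e-9) {
  r_imp <- degree_assortativity(g)
  r_or <- oracle_assortativity(g)
  if (is.na(r_or)) expect_true(is.na(r_imp)) else expect_equal(r_imp, r_or, tolerance = tol)
  expect_equal(local_clustering(g), oracle_local_clustering(g), tolerance = tol)
  expect_equal(transitivity_global(g), oracle_transitivity(g), tolerance = tol)
  D <- oracle_apsp(g)
  gs <- geodesic_stats(g)
  expect_equal(gs$mean, mean(D[upper.tri(D)]), tolerance = tol)
  expect_equal(gs$diameter, max(D[upper.tri(D)]), tolerance = tol)
  expect_equal(closeness_all(g), oracle_closeness(g, D), tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(betweenness_all(g), oracle_betweenness(g, D), tolerance = tol,
               ignore_attr = TRUE)
  # iterate past the comparison tolerance so the check is about the vector,
  # not the stopping rule
  expect_equal(eigenvector_all(g, tol = 1e-12), oracle_eigenvector(g),
               tolerance = tol, ignore_attr = TRUE)
}
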