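#' Controller configuration for a rewiring run
#'
#' Each targeted rewiring run is governed by three parameters beyond the
#' algorithm itself. The *window* is the number of attempts between property
#' snapshots and convergence checks: by default 20% of the edge count for
#' the assortativity and clustering algorithms and 10% for the geodesic
#' algorithm (whose attempts are much more expensive). The *convergence*
#' threshold stops a run that is no longer making progress: with the default
#' 0.9, at least 10% of the attempts in any completed window must have
#' committed for the run to continue. *max_attempts* caps the run at ten
#' times the edge count (assortativity, clustering) or at the edge count
#' (geodesic).
#'
#' @param algorithm one of `"assortativity"`, `"clustering"`, `"geodesic"`.
#' @param edges edge count `M` of the network to be rewired; used to derive
#'   default `window` and `max_attempts`.
#' @param window snapshot/convergence window size in attempts (positive
#'   integer); default as above.
#' @param convergence failure-rate threshold in `(0, 1)`; a run stops when
#'   a completed window has fewer than `(1 - convergence) * window`
#'   successful swaps.
#' @param max_attempts attempt cap (positive integer); default as above.
#' @param seed optional RNG seed making the run deterministic.
#' @return A list of class `rewiring_config`.
#' @examples
#' rewiring_config("geodesic", edges = 1100)
#' @export
rewiring_config <- function(algorithm = c("assortativity", "clustering", "geodesic"),
                            edges, window = NULL, convergence = 0.9,
                            max_attempts = NULL, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (missing(edges) && (is.null(window) || is.null(max_attempts))) {
    stop("supply `edges` (to derive defaults) or both `window` and `max_attempts`")
  }
  window <- window %||% ceiling(if (algorithm == "geodesic") 0.1 * edges else 0.2 * edges)
  max_attempts <- max_attempts %||% (if (algorithm == "geodesic") edges else 10L * edges)
  window <- as.integer(window)
  max_attempts <- as.integer(max_attempts)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  if (is.na(max_attempts) || max_attempts < 1L) stop("max_attempts must be a positive integer")
  if (!is.numeric(convergence) || convergence <= 0 || convergence >= 1) {
    stop("convergence must lie strictly between 0 and 1")
  }
  structure(
    list(algorithm = algorithm, window = window, convergence = convergence,
         max_attempts = max_attempts, seed = seed),
    class = "rewiring_config"
  )
}

#' @export
print.rewiring_config <- function(x, ...) {
  cat(sprintf(
    "<rewiring_config: %s, window = %d, convergence = %.2f, max_attempts = %d, seed = %s>\n",
    x$algorithm, x$window, x$convergence, x$max_attempts,
    if (is.null(x$seed)) "none" else format(x$seed)
  ))
  invisible(x)
}

# Uniform outcome container for a single rewiring attempt. `network` is the
# (possibly unchanged) graph; `committed` is TRUE iff reason == "committed".
attempt_outcome <- function(network, reason, detail = list()) {
  list(network = network, committed = identical(reason, "committed"),
       reason = reason, detail = detail)
}

# --- assortativity ----------------------------------------------------------

# Deterministic core of the assortativity swap: given two existing disjoint
# edges (a,b) and (c,d), propose the endpoint pairing that joins the two
# highest-degree nodes together and the two lowest-degree nodes together,
# and commit only if that pairing strictly raises the sum of
# endpoint-degree products, introduces no duplicate edge, and keeps the
# graph connected. Degrees of all four nodes are preserved on commit.
eval_assortativity_swap <- function(net, a, b, c_, d_, deg = igraph::degree(net)) {
  cur <- deg[a] * deg[b] + deg[c_] * deg[d_]
  alt1 <- deg[a] * deg[c_] + deg[b] * deg[d_]  # pairing (a,c), (b,d)
  alt2 <- deg[a] * deg[d_] + deg[b] * deg[c_]  # pairing (a,d), (b,c)
  best <- max(alt1, alt2)
  if (best <= cur) {
    return(attempt_outcome(net, "already-optimal",
                           list(jk_before = cur, jk_after = cur)))
  }
  pairs <- if (alt1 >= alt2) rbind(c(a, c_), c(b, d_)) else rbind(c(a, d_), c(b, c_))
  if (igraph::are_adjacent(net, pairs[1, 1], pairs[1, 2]) ||
      igraph::are_adjacent(net, pairs[2, 1], pairs[2, 2])) {
    return(attempt_outcome(net, "duplicate-edge"))
  }
  eids <- igraph::get_edge_ids(net, c(a, b, c_, d_))
  g2 <- igraph::add_edges(igraph::delete_edges(net, eids), t(pairs))
  if (!igraph::is_connected(g2)) {
    return(attempt_outcome(net, "would-disconnect"))
  }
  attempt_outcome(g2, "committed",
                  list(jk_before = cur, jk_after = best,
                       removed = rbind(c(a, b), c(c_, d_)), added = pairs))
}

#' Attempt one assortativity-increasing edge swap
#'
#' Selects two distinct edges uniformly at random. If they share a node the
#' attempt is a `degenerate-selection` failure. Otherwise the four endpoint
#' degrees are ranked and the swap that connects the two highest-degree
#' nodes to each other (and the two lowest to each other) is proposed; it is
#' committed only if it strictly increases the sum of endpoint-degree
#' products (ties count as `already-optimal`), creates no duplicate edge,
#' and leaves the network connected. Node degrees are unchanged either way.
#'
#' @param net connected simple igraph object with at least 2 edges.
#' @return An attempt outcome: a list with `network` (the new graph if
#'   committed, the input otherwise), `committed`, `reason` (one of
#'   `committed`, `already-optimal`, `duplicate-edge`, `would-disconnect`,
#'   `degenerate-selection`), and `detail` (for committed swaps, the
#'   endpoint-degree product sums before and after).
#' @export
attempt_assortativity_swap <- function(net) {
  m <- igraph::ecount(net)
  if (m < 2L) stop("need at least 2 edges to attempt a swap")
  ei <- sample.int(m, 2L)
  e <- igraph::ends(net, ei, names = FALSE)
  nodes <- c(e[1, ], e[2, ])
  if (length(unique(nodes)) < 4L) {
    return(attempt_outcome(net, "degenerate-selection"))
  }
  eval_assortativity_swap(net, e[1, 1], e[1, 2], e[2, 1], e[2, 2])
}

# --- clustering -------------------------------------------------------------

# Deterministic core of the clustering rewire on the 5-node path
# p - u - A - v - q (all distinct): break the end edges (p,u) and (v,q),
# close the triangle by adding (u,v), and add (p,q) to preserve degrees.
# Commit only if no duplicate edge arises, the graph stays connected, and
# the mean local clustering coefficient strictly increases (the removals
# may destroy triangles elsewhere, so the full effect is evaluated).
eval_clustering_rewire <- function(net, a, u, v, p, q, cbar = NULL) {
  if (igraph::are_adjacent(net, u, v) || igraph::are_adjacent(net, p, q)) {
    return(attempt_outcome(net, "duplicate-edge"))
  }
  eids <- igraph::get_edge_ids(net, c(p, u, v, q))
  g2 <- igraph::add_edges(igraph::delete_edges(net, eids), c(u, v, p, q))
  if (!igraph::is_connected(g2)) {
    return(attempt_outcome(net, "would-disconnect"))
  }
  cb0 <- cbar %||% mean_local_clustering(net)
  cb1 <- mean_local_clustering(g2)
  if (cb1 <= cb0) {
    return(attempt_outcome(net, "no-improvement",
                           list(cbar_before = cb0, cbar_after = cb0)))
  }
  attempt_outcome(g2, "committed",
                  list(cbar_before = cb0, cbar_after = cb1,
                       path = c(p, u, a, v, q)))
}

#' Attempt one clustering-increasing rewire (triangle closure)
#'
#' Selects a node `A` with degree at least 2 uniformly at random, then two
#' distinct incident edges giving neighbours `u` and `v`, then extends one
#' step beyond each (uniformly among eligible neighbours) to form a simple
#' five-node path `p - u - A - v - q` with all nodes distinct; if no such
#' extension exists the attempt fails with `no-valid-path`. The end edges
#' `(p, u)` and `(v, q)` are broken, the central triangle is closed by
#' adding `(u, v)`, and `(p, q)` is added to preserve all five degrees. The
#' rewire is committed only if neither added edge already exists, the
#' network stays connected, and the mean local clustering coefficient
#' strictly increases (edge breaking can destroy triangles, so the net
#' effect is checked, not assumed).
#'
#' @param net connected simple igraph object.
#' @param cbar current mean local clustering of `net`, if already known
#'   (avoids recomputation inside long runs); computed when `NULL`.
#' @return An attempt outcome (see [attempt_assortativity_swap()]); for
#'   committed rewires `detail` holds `cbar_before` and `cbar_after`.
#' @export
attempt_clustering_rewire <- function(net, cbar = NULL) {
  deg <- igraph::degree(net)
  cand <- which(deg >= 2)
  if (length(cand) == 0L) {
    return(attempt_outcome(net, "no-valid-path"))
  }
  a <- cand[sample.int(length(cand), 1L)]
  nb <- as.integer(igraph::neighbors(net, a))
  uv <- nb[sample.int(length(nb), 2L)]
  u <- uv[1L]; v <- uv[2L]
  pc <- setdiff(as.integer(igraph::neighbors(net, u)), c(a, v))
  if (length(pc) == 0L) return(attempt_outcome(net, "no-valid-path"))
  p <- pc[sample.int(length(pc), 1L)]
  qc <- setdiff(as.integer(igraph::neighbors(net, v)), c(a, u, p))
  if (length(qc) == 0L) return(attempt_outcome(net, "no-valid-path"))
  q <- qc[sample.int(length(qc), 1L)]
  eval_clustering_rewire(net, a, u, v, p, q, cbar = cbar)
}

# --- geodesic ---------------------------------------------------------------

# Deterministic core of the geodesic shortcut rewire: for distinct nodes
# A, B with chosen neighbours C (of A) and D (of B), tentatively replace
# edges (A,C) and (B,D) by (A,B) and (C,D), and commit only if the mean
# geodesic strictly decreases and the graph stays connected.
eval_geodesic_rewire <- function(net, a, b, c_, d_, dist = NULL) {
  if (length(unique(c(a, b, c_, d_))) < 4L) {
    return(attempt_outcome(net, "degenerate-selection"))
  }
  if (igraph::are_adjacent(net, a, b) || igraph::are_adjacent(net, c_, d_)) {
    return(attempt_outcome(net, "duplicate-edge"))
  }
  D <- dist %||% igraph::distances(net)
  eids <- igraph::get_edge_ids(net, c(a, c_, b, d_))
  g2 <- igraph::add_edges(igraph::delete_edges(net, eids), c(a, b, c_, d_))
  if (!igraph::is_connected(g2)) {
    return(attempt_outcome(net, "would-disconnect"))
  }
  up <- upper.tri(D)
  l1 <- mean(D[up])
  D2 <- igraph::distances(g2)
  l2 <- mean(D2[up])
  if (l2 >= l1) {
    return(attempt_outcome(net, "no-improvement",
                           list(geodesic_before = l1, geodesic_after = l1)))
  }
  attempt_outcome(g2, "committed",
                  list(geodesic_before = l1, geodesic_after = l2,
                       distances = D2))
}

#' Attempt one geodesic-decreasing rewire (distance shortcut)
#'
#' Samples an unordered node pair `(A, B)` with probability proportional to
#' their current shortest-path distance (so distant pairs are favoured but
#' no distance has zero probability), then a neighbour `C` of `A` and a
#' neighbour `D` of `B`, each with probability proportional to degree. The
#' attempt fails with `degenerate-selection` unless `A`, `B`, `C`, `D` are
#' distinct, and with `duplicate-edge` if `(A, B)` or `(C, D)` already
#' exists. Otherwise edges `(A, C)` and `(B, D)` are tentatively replaced by
#' `(A, B)` and `(C, D)` (degrees preserved); the mean geodesic is
#' recomputed and the rewire is committed only if it strictly decreased and
#' the network stayed connected, and reverted otherwise.
#'
#' @param net connected simple igraph object.
#' @param dist current all-pairs distance matrix of `net`, if already known;
#'   computed when `NULL`. For committed rewires the updated matrix is
#'   returned in `detail$distances` so callers can maintain the table.
#' @return An attempt outcome (see [attempt_assortativity_swap()]); for
#'   committed rewires `detail` holds `geodesic_before`, `geodesic_after`
#'   and the new `distances` matrix.
#' @export
attempt_geodesic_rewire <- function(net, dist = NULL) {
  n <- igraph::vcount(net)
  if (n < 4L) stop("need at least 4 nodes for a geodesic rewire")
  D <- dist %||% igraph::distances(net)
  if (any(!is.finite(D))) stop("graph is disconnected")
  up_idx <- which(upper.tri(D))
  pick <- up_idx[sample.int(length(up_idx), 1L, prob = D[up_idx])]
  a <- ((pick - 1L) %% n) + 1L
  b <- ((pick - 1L) %/% n) + 1L
  deg <- igraph::degree(net)
  na_ <- as.integer(igraph::neighbors(net, a))
  c_ <- na_[sample.int(length(na_), 1L, prob = deg[na_])]
  nb_ <- as.integer(igraph::neighbors(net, b))
  d_ <- nb_[sample.int(length(nb_), 1L, prob = deg[nb_])]
  eval_geodesic_rewire(net, a, b, c_, d_, dist = D)
}

# --- controller -------------------------------------------------------------

#' Run a full targeted rewiring trajectory
#'
#' Repeatedly applies the configured attempt operator. Every attempt --
#' committed or not -- counts towards the convergence window. The property
#' panel ([measure_all()]) is recorded at attempt 0 and after every
#' `window` attempts; the run terminates when a completed window had fewer
#' than `(1 - convergence) * window` successful swaps, or at
#' `max_attempts`, whichever comes first. A terminal snapshot is always
#' recorded, so a run cut off mid-window still reports its final state.
#' Given the same seed, configuration and starting network, the trajectory
#' is identical.
#'
#' @param start connected simple igraph object.
#' @param config a [rewiring_config()].
#' @return A list with `network` (the rewired graph), `trajectory` (a
#'   `data.frame` with columns `attempt`, `successes`, then the
#'   [measure_all()] property columns; attributes `algorithm`, `config` and
#'   `termination` record run metadata) and `termination` (`"converged"` or
#'   `"max-attempts"`).
#' @examples
#' set.seed(7)
#' g <- giant_component(configuration_model(
#'   synth_degree_sequence(30, 4, 0.2, seed = 7)))
#' run <- run_rewiring(g, rewiring_config("assortativity", igraph::ecount(g),
#'                                        seed = 7))
#' run$trajectory[, c("attempt", "successes", "assortativity")]
#' @export
run_rewiring <- function(start, config) {
  stopifnot(igraph::is_igraph(start), inherits(config, "rewiring_config"))
  if (!igraph::is_connected(start)) stop("starting network must be connected")
  if (igraph::any_loop(start) || igraph::any_multiple(start)) {
    stop("starting network must be simple")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- start
  alg <- config$algorithm
  w <- config$window
  cap <- config$max_attempts
  fail_floor <- (1 - config$convergence) * w

  cbar <- if (alg == "clustering") mean_local_clustering(g) else NULL
  dist <- if (alg == "geodesic") igraph::distances(g) else NULL

  snaps <- vector("list", cap %/% w + 2L)
  n_snap <- 0L
  take <- function(attempt, successes) {
    n_snap <<- n_snap + 1L
    snaps[[n_snap]] <<- cbind(attempt = attempt, successes = successes,
                              measure_all(g))
  }
  take(0L, 0L)

  successes <- 0L
  window_successes <- 0L
  i <- 0L
  termination <- "max-attempts"
  while (i < cap) {
    i <- i + 1L
    out <- switch(alg,
      assortativity = attempt_assortativity_swap(g),
      clustering = attempt_clustering_rewire(g, cbar = cbar),
      geodesic = attempt_geodesic_rewire(g, dist = dist)
    )
    if (out$committed) {
      g <- out$network
      successes <- successes + 1L
      window_successes <- window_successes + 1L
      if (alg == "clustering") cbar <- out$detail$cbar_after
      if (alg == "geodesic") dist <- out$detail$distances
    }
    if (i %% w == 0L) {
      take(i, successes)
      if (window_successes < fail_floor) {
        termination <- "converged"
        break
      }
      window_successes <- 0L
    }
  }
  if (snaps[[n_snap]][1L, "attempt"] != i) take(i, successes)

  traj <- do.call(rbind, snaps[seq_len(n_snap)])
  rownames(traj) <- NULL
  attr(traj, "algorithm") <- alg
  attr(traj, "config") <- config
  attr(traj, "termination") <- termination
  list(network = g, trajectory = traj, termination = termination)
}
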