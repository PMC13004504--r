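#' Degree assortativity coefficient
#'
#' Pearson correlation of the degrees at the two ends of every edge, taken
#' over both orientations of each edge (Newman's degree assortativity).
#' Positive values mean well-connected nodes tend to attach to other
#' well-connected nodes.
#'
#' @param net an undirected simple igraph object with at least one edge.
#' @return The coefficient `r` in `[-1, 1]`, or `NA` when the endpoint
#'   degrees have zero variance (degree-regular graphs), where the
#'   correlation is undefined.
#' @examples
#' degree_assortativity(toy_graph("star4"))   # -1
#' degree_assortativity(toy_graph("cycle6"))  # NA: regular graph
#' @export
degree_assortativity <- function(net) {
  if (igraph::ecount(net) == 0L) stop("assortativity undefined on an edgeless graph")
  r <- igraph::assortativity_degree(net, directed = FALSE)
  if (is.nan(r)) NA_real_ else r
}

#' Local clustering coefficients
#'
#' The local clustering coefficient of a node is the fraction of its
#' neighbour pairs that are themselves connected. Nodes with degree below 2
#' have no neighbour pairs and contribute a coefficient of 0 (they are
#' included, not dropped, so the mean is defined on every graph).
#'
#' @param net an igraph object.
#' @param v vertices to report (default all).
#' @return `local_clustering()`: numeric vector of per-node coefficients in
#'   `[0, 1]`. `mean_local_clustering()`: their mean over all nodes.
#' @examples
#' local_clustering(toy_graph("paw"))       # 1, 1, 1/3, 0
#' mean_local_clustering(toy_graph("paw"))  # 7/12
#' @export
local_clustering <- function(net, v = igraph::V(net)) {
  out <- igraph::transitivity(net, type = "local", vids = v, isolates = "zero")
  as.numeric(out)
}

#' @rdname local_clustering
#' @export
mean_local_clustering <- function(net) {
  mean(local_clustering(net))
}

#' Global clustering coefficient (transitivity)
#'
#' Three times the number of triangles divided by the number of connected
#' triples (paths of length two). Defined as 0 on graphs with no connected
#' triples.
#'
#' @param net an igraph object.
#' @return Transitivity in `[0, 1]`.
#' @examples
#' transitivity_global(toy_graph("paw"))  # 3/5
#' @export
transitivity_global <- function(net) {
  t <- igraph::transitivity(net, type = "global")
  if (is.nan(t)) 0 else t
}

#' Geodesic statistics
#'
#' All-pairs shortest-path lengths by breadth-first traversal from every
#' node. The mean geodesic averages over unordered distinct pairs; the
#' diameter is the maximum.
#'
#' @param net a connected igraph object with at least 2 nodes.
#' @return A list with `mean`, `diameter` and the full symmetric
#'   `distances` matrix (hops).
#' @examples
#' geodesic_stats(toy_graph("path3"))$mean  # 4/3
#' @export
geodesic_stats <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("geodesic statistics need at least 2 nodes")
  D <- igraph::distances(net)
  if (any(!is.finite(D))) stop("graph is disconnected; geodesics undefined")
  up <- D[upper.tri(D)]
  list(mean = mean(up), diameter = max(up), distances = D)
}

#' Closeness centrality of every node
#'
#' `(n - 1) / farness`: the inverse of a node's average shortest-path
#' distance to all other nodes, so that central nodes score high.
#'
#' @param net a connected igraph object with at least 2 nodes.
#' @param distances optional precomputed all-pairs distance matrix (as from
#'   [geodesic_stats()]); computed if missing.
#' @return Numeric vector of per-node closeness values in `(0, 1]`.
#' @examples
#' closeness_all(toy_graph("path3"))  # 2/3, 1, 2/3
#' @export
closeness_all <- function(net, distances = NULL) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("closeness needs at least 2 nodes")
  D <- distances %||% igraph::distances(net)
  if (any(!is.finite(D))) stop("graph is disconnected; closeness undefined")
  (n - 1) / rowSums(D)
}

#' Betweenness centrality of every node
#'
#' Shortest-path betweenness with endpoint exclusion and fractional
#' counting over multiple shortest paths, normalized by
#' `(n - 1)(n - 2) / 2` so values lie in `[0, 1]`.
#'
#' @param net a connected igraph object.
#' @return Numeric vector of per-node normalized betweenness values.
#' @examples
#' betweenness_all(toy_graph("path3"))  # 0, 1, 0
#' @export
betweenness_all <- function(net) {
  if (!igraph::is_connected(net)) stop("graph is disconnected; betweenness undefined")
  n <- igraph::vcount(net)
  if (n < 3L) return(rep(0, n))
  igraph::betweenness(net, directed = FALSE) / ((n - 1) * (n - 2) / 2)
}

#' Eigenvector centrality of every node
#'
#' Entries of the principal eigenvector of the adjacency matrix, normalized
#' to unit Euclidean norm, so that a node's score grows with the scores of
#' its neighbours. Computed by shifted power iteration (`A + I`, which has
#' the same principal eigenvector and converges on bipartite graphs too) to
#' relative tolerance `1e-10` with an iteration cap of `1e5`.
#'
#' @param net a connected igraph object.
#' @param tol convergence tolerance on the max absolute change of the unit
#'   vector between iterations.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return Numeric vector of non-negative values with `sum(x^2) == 1`.
#' @examples
#' eigenvector_all(toy_graph("path3"))  # 1/2, 1/sqrt(2), 1/2
#' @export
eigenvector_all <- function(net, tol = 1e-10, max_iter = 1e5) {
  if (!igraph::is_connected(net)) stop("graph is disconnected; eigenvector centrality undefined")
  n <- igraph::vcount(net)
  if (n == 1L) return(1)
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + v
    w <- w / sqrt(sum(w * w))
    if (max(abs(w - v)) < tol) return(w)
    v <- w
  }
  stop("eigenvector power iteration failed to converge")
}

#' Gini coefficient of a non-negative distribution
#'
#' Normalized mean absolute pairwise difference,
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, a variation measure that
#' behaves well for the skewed, non-normal distributions typical of network
#' centralities. Computed via the O(n log n) sorted form; equals the
#' definitional double sum. `G = 0` for a constant vector and, by
#' convention, when the mean is 0.
#'
#' @param x numeric vector of non-negative values, length at least 1.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' gini(c(5, 5, 5, 5))  # 0
#' gini(c(0, 0, 0, 1))  # 0.75
#' gini(c(1, 2, 3, 4))  # 0.25
#' @export
gini <- function(x) {
  if (length(x) == 0L) stop("gini needs at least one value")
  if (anyNA(x) || any(!is.finite(x))) stop("gini input must be finite")
  if (any(x < 0)) stop("gini is defined here for non-negative values only")
  n <- length(x)
  s <- sum(x)
  if (s == 0) return(0)
  xs <- sort(x)
  max(0, 2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n)
}

# Stable column order of a property vector; documented contract for all
# trajectory CSV output.
property_vector_names <- function() {
  c("n", "m", "degree_mean", "degree_gini", "assortativity",
    "local_clustering_mean", "transitivity", "geodesic_mean", "diameter",
    "closeness_mean", "closeness_gini", "betweenness_mean",
    "betweenness_gini", "eigenvector_mean", "eigenvector_gini")
}

#' Measure all tracked structural properties at once
#'
#' One consistent snapshot of the property panel tracked along rewiring
#' trajectories: size, mean and Gini of degree, degree assortativity, mean
#' local clustering, transitivity, mean geodesic and diameter, and mean and
#' Gini of closeness, betweenness and eigenvector centrality. The all-pairs
#' distance table is computed once and shared by the geodesic and closeness
#' fields.
#'
#' @param net a connected simple igraph object with at least 2 nodes.
#' @return A one-row `data.frame` with the columns listed above, in a fixed
#'   order. `assortativity` is `NA` on degree-regular graphs (undefined
#'   correlation); when serialized to CSV the `NA` becomes an empty cell.
#' @examples
#' measure_all(toy_graph("triangle"))
#' @export
measure_all <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::any_loop(net) || igraph::any_multiple(net)) {
    stop("measure_all expects a simple graph")
  }
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  geo <- geodesic_stats(net)
  clo <- closeness_all(net, distances = geo$distances)
  btw <- betweenness_all(net)
  eig <- eigenvector_all(net)
  out <- data.frame(
    n = n,
    m = m,
    degree_mean = 2 * m / n,
    degree_gini = gini(deg),
    assortativity = degree_assortativity(net),
    local_clustering_mean = mean_local_clustering(net),
    transitivity = transitivity_global(net),
    geodesic_mean = geo$mean,
    diameter = geo$diameter,
    closeness_mean = mean(clo),
    closeness_gini = gini(clo),
    betweenness_mean = mean(btw),
    betweenness_gini = gini(btw),
    eigenvector_mean = mean(eig),
    eigenvector_gini = gini(eig)
  )
  out[, property_vector_names()]
}

# Sum over edges of the product of endpoint degrees. Because every
# degree-preserving swap leaves the marginal degree moments unchanged, the
# change in assortativity r after a swap has the same sign as the change in
# this sum.
#' Sum of endpoint-degree products over all edges
#'
#' For degree-preserving swaps the marginal moments of the endpoint-degree
#' distribution are invariant, so the sign of the change in this sum equals
#' the sign of the change in degree assortativity.
#'
#' @param net an igraph object.
#' @return A single number, `sum over edges e of j_e * k_e`.
#' @export
edge_degree_product_sum <- function(net) {
  if (igraph::ecount(net) == 0L) return(0)
  deg <- igraph::degree(net)
  e <- igraph::ends(net, igraph::E(net), names = FALSE)
  sum(deg[e[, 1L]] * deg[e[, 2L]])
}
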