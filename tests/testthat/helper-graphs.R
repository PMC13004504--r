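# Small-graph generators used across the suite.

# All labeled connected graphs on exactly n nodes (n <= 6 is practical:
# 4, 38, 728 and 26704 graphs for n = 3..6), enumerated as edge subsets of
# the complete graph and filtered for connectivity with a hand-rolled
# union-find (independent of igraph).
all_connected_edge_sets <- function(n) {
  pairs <- t(utils::combn(n, 2))
  K <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^K - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1L))) != 0L)
    if (length(sel) < n - 1L) next
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    for (e in sel) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, 0L))) == 1L) {
      out[[length(out) + 1L]] <- pairs[sel, , drop = FALSE]
    }
  }
  out
}

graph_from_pairs <- function(pairs, n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, t(pairs))
}

# Random connected Erdos-Renyi graph by rejection.
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) return(g)
  }
}

# A connected configuration-model giant component from the package's own
# lognormal generator; the standard medium-size test network.
test_network <- function(n = 150, k = 5.5, g = 0.25, seed = 42) {
  set.seed(seed)
  giant_component(configuration_model(
    synth_degree_sequence(n, k, g, seed = seed)
  ))
}

edge_set_of <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- t(apply(el, 1, sort))
  sort(paste(el[, 1], el[, 2]))
}
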