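#' Read an undirected edge list from a plain-text file
#'
#' One edge per line, two node tokens separated by whitespace or commas;
#' lines starting with `#` and blank lines are ignored. The graph is
#' simplified on read: self-loops are dropped and parallel edges collapsed.
#' Node tokens are mapped to contiguous internal vertex ids in order of first
#' appearance; the original labels are kept in the vertex attribute `name`,
#' so the mapping is retrievable with `igraph::V(net)$name`. The result need
#' not be connected (see [giant_component()]).
#'
#' @param path file path.
#' @return An undirected simple igraph object.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "c a"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no edges found in '", path, "'")
  toks <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge on line %d of '%s': '%s'",
                 keep[bad[1L]], path, lines[keep[bad[1L]]]))
  }
  from <- vapply(toks, `[`, "", 1L)
  to <- vapply(toks, `[`, "", 2L)
  labels <- unique(as.vector(rbind(from, to)))
  el <- cbind(match(from, labels), match(to, labels))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- labels
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a plain-text edge list
#'
#' Emits one `"u v"` pair per line, using the vertex `name` attribute when
#' present and internal vertex ids otherwise. Writing then reading
#' reproduces the edge set exactly.
#'
#' @param net an igraph object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net, names = !is.null(igraph::V(net)$name))
  writeLines(paste(el[, 1L], el[, 2L]), con = path)
  invisible(path)
}

#' Configuration-model random graph from a degree sequence
#'
#' Performs uniform random stub matching on the degree sequence, then
#' removes self-loops and collapses parallel edges so the result is a simple
#' graph. Node degrees in the result are therefore less than or equal to the
#' requested degrees (for sequences whose maximum degree is small relative
#' to the number of nodes the deficit is slight). The result may be
#' disconnected; use [giant_component()] to extract a connected starting
#' network for rewiring.
#'
#' Randomness is drawn from R's global RNG; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param seq a [degree_sequence()] (or bare integer vector of degrees); the
#'   degrees must sum to an even number.
#' @return An undirected simple igraph object.
#' @examples
#' set.seed(1)
#' g <- configuration_model(degree_sequence(c(2, 2, 2)))
#' @export
configuration_model <- function(seq) {
  seq <- degree_sequence(seq, name = if (inherits(seq, "degree_sequence"))
    seq$name else "sequence")
  if (sum(seq$degrees) %% 2L != 0L) {
    stop("degree sequence sums to an odd number; cannot match stubs")
  }
  g <- igraph::sample_degseq(seq$degrees, method = "configuration")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Extract the giant (largest connected) component
#'
#' Returns the induced subgraph on the largest connected node set,
#' relabelled to contiguous vertex ids. If several components tie for the
#' largest size, the one containing the smallest original vertex id is
#' taken, making the choice deterministic. Original vertex ids are kept in
#' the vertex attribute `orig_index` (and original labels, when present, in
#' `name`).
#'
#' @param net an igraph object.
#' @return A connected igraph object.
#' @examples
#' g <- igraph::graph_from_edgelist(
#'   cbind(c(1, 2, 3, 4), c(2, 3, 1, 5)), directed = FALSE)
#' giant_component(g)
#' @export
giant_component <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("empty graph has no giant component")
  comp <- igraph::components(net)
  best_size <- max(comp$csize)
  cands <- which(comp$csize == best_size)
  if (length(cands) > 1L) {
    first_member <- vapply(cands, function(cc) min(which(comp$membership == cc)), 0L)
    cands <- cands[which.min(first_member)]
  }
  keep <- which(comp$membership == cands[1L])
  igraph::V(net)$orig_index <- seq_len(igraph::vcount(net))
  igraph::induced_subgraph(net, keep)
}
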