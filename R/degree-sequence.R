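#' Degree sequence objects
#'
#' A degree sequence is the multiset of node degrees of a graph. It is the
#' only information carried from an empirical network into a rewiring
#' experiment: random starting networks are drawn from it with
#' [configuration_model()], and every rewiring step preserves it exactly.
#'
#' @param degrees integer vector of node degrees; every degree must be a
#'   whole number `>= 1` (isolated nodes carry no information for rewiring
#'   and are disallowed).
#' @param name identifier for the sequence, used in file names and run
#'   metadata.
#' @return An object of class `degree_sequence`: a list with elements
#'   `name` and `degrees`.
#' @examples
#' degree_sequence(c(3, 1, 1, 1), name = "star4")
#' @export
degree_sequence <- function(degrees, name = "sequence") {
  if (inherits(degrees, "degree_sequence")) {
    degrees$name <- name
    return(degrees)
  }
  if (length(degrees) == 0L) stop("degree sequence must not be empty")
  if (!is.numeric(degrees) || anyNA(degrees) || any(!is.finite(degrees))) {
    stop("degrees must be finite numbers")
  }
  if (any(degrees != round(degrees))) stop("degrees must be whole numbers")
  if (any(degrees < 1)) stop("every degree must be >= 1")
  structure(
    list(name = as.character(name)[1L], degrees = as.integer(degrees)),
    class = "degree_sequence"
  )
}

#' @export
print.degree_sequence <- function(x, ...) {
  cat(sprintf(
    "<degree_sequence '%s': n = %d, mean degree = %.2f, sum = %d>\n",
    x$name, length(x$degrees), mean(x$degrees), sum(x$degrees)
  ))
  invisible(x)
}

#' Extract the degree sequence of a network
#'
#' @param net an igraph object (undirected simple graph).
#' @param name identifier for the resulting sequence.
#' @return A [degree_sequence()] with one entry per node; the entries sum to
#'   twice the edge count.
#' @examples
#' degree_sequence_of(toy_graph("paw"), name = "paw")
#' @export
degree_sequence_of <- function(net, name = "sequence") {
  stopifnot(igraph::is_igraph(net))
  degree_sequence(igraph::degree(net), name = name)
}

#' Read and write degree-sequence files
#'
#' The file format is one positive integer per line; blank lines and lines
#' starting with `#` are ignored on read.
#'
#' @param path file path.
#' @param name identifier for the sequence (defaults to the file name).
#' @return `read_degree_sequence()` returns a [degree_sequence()];
#'   `write_degree_sequence()` returns `path` invisibly.
#' @export
read_degree_sequence <- function(path, name = NULL) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no degrees found in '", path, "'")
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1L]]
    stop(sprintf("malformed degree on line %d of '%s': '%s'",
                 bad, path, lines[bad]))
  }
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  degree_sequence(vals, name = name)
}

#' @rdname read_degree_sequence
#' @param seq a [degree_sequence()] (or bare integer vector).
#' @export
write_degree_sequence <- function(seq, path) {
  seq <- degree_sequence(seq, name = if (inherits(seq, "degree_sequence"))
    seq$name else "sequence")
  writeLines(as.character(seq$degrees), con = path)
  invisible(path)
}
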