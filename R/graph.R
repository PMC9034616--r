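#' Connected simple graph (heavy-atom skeleton)
#'
#' Light container for a hydrogen-suppressed skeleton.  Vertices are numbered
#' `1..n`; edges are stored as an `m x 2` integer matrix with each row
#' `(i, j)`, `i < j`, sorted lexicographically.  This edge order is frozen at
#' creation: the bond-multiplicity lists of stage 3 index into it.
#'
#' @param n vertex count.
#' @param edges `m x 2` matrix of vertex pairs (any orientation/order; they
#'   are normalised), or NULL for an edgeless graph.
#' @return an object of class `simple_graph` with fields `n`, `edges`,
#'   `degree`.
#' @examples
#' simple_graph(5, cbind(1:5, c(2:5, 1)))   # the 5-cycle
#' @export
simple_graph <- function(n, edges = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(), 0L, 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
      stop("parallel edges are not allowed in a simple graph")
  }
  deg <- tabulate(edges, nbins = n)
  structure(list(n = n, edges = edges, degree = deg), class = "simple_graph")
}

#' @export
print.simple_graph <- function(x, ...) {
  cat("simple_graph:", x$n, "vertices,", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat("  ", paste(apply(x$edges, 1L, paste, collapse = "-"),
                    collapse = " "), "\n")
  invisible(x)
}

# adjacency list (list of integer vectors), 1-based
adj_list <- function(g) {
  a <- rep(list(integer()), g$n)
  for (i in seq_len(nrow(g$edges))) {
    u <- g$edges[i, 1L]; v <- g$edges[i, 2L]
    a[[u]] <- c(a[[u]], v)
    a[[v]] <- c(a[[v]], u)
  }
  lapply(a, sort)
}

is_connected_graph <- function(g) {
  if (g$n == 1L) return(TRUE)
  a <- adj_list(g)
  seen <- logical(g$n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- a[[v]][!seen[a[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# index lookup: edge (i,j) -> row of g$edges
edge_index_map <- function(g) {
  key <- g$edges[, 1L] * (g$n + 1L) + g$edges[, 2L]
  stats::setNames(seq_along(key), key)
}

edge_key <- function(a, b, n) pmin(a, b) * (n + 1L) + pmax(a, b)

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}
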