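#' Generate connected simple skeleton graphs
#'
#' Stage 1: produces exactly one representative of every isomorphism class
#' of connected simple graphs on `n` vertices with edge count inside the
#' formula's budget and every degree at most the largest valence present.
#' Generation is by canonical augmentation: graphs grow one vertex at a
#' time and a graph is kept only when it is reached along its canonical
#' construction path, so no list of previously seen graphs is ever stored.
#' Generation is deterministic; the output is independent of any random
#' seed.
#'
#' Skeleton-level filters (5-ring bounds, planarity, badlist 9) prune here,
#' before graphs reach the element stage.
#'
#' @param x a `mol_formula`, or an `edge_budget` (then `n` and `max_degree`
#'   are required).
#' @param filters a [filter_config()].
#' @param n,max_degree vertex count and degree cap; derived from the formula
#'   when `x` is a `mol_formula`.
#' @param callback optional function receiving each `simple_graph` as it is
#'   produced; when supplied, graphs are not accumulated and the surviving
#'   count is returned.
#' @param collect_cap abort if more than this many graphs would be stored.
#' @return list of [simple_graph()] objects (or a count in callback mode).
#' @examples
#' f <- parse_formula("C4H4O")
#' length(generate_simple_graphs(f))
#' @export
generate_simple_graphs <- function(x, filters = filter_config(),
                                   n = NULL, max_degree = NULL,
                                   callback = NULL, collect_cap = 2e6) {
  if (inherits(x, "mol_formula")) {
    b <- edge_budget(x)
    n <- x$n
    max_degree <- b$max_degree
  } else if (inherits(x, "edge_budget")) {
    b <- x
    if (is.null(n)) stop("n is required when passing an edge_budget")
    if (is.null(max_degree)) max_degree <- b$max_degree
  } else stop("x must be a mol_formula or an edge_budget")
  if (!b$feasible) return(if (is.null(callback)) list() else 0)

  keep <- function(g) {
    if (!is.null(filters$pentagon_bounds)) {
      p5 <- count_cycles(g, 5L)
      if (p5 < filters$pentagon_bounds[1L] || p5 > filters$pentagon_bounds[2L])
        return(FALSE)
    }
    if (filters$planar_only && !is_planar(g)) return(FALSE)
    if (9L %in% filters$badlists && !passes_B9(g)) return(FALSE)
    TRUE
  }

  if (!is.null(callback)) {
    cnt <- 0
    cb <- function(edges) {
      g <- simple_graph_from_engine(n, edges)
      if (keep(g)) { cnt <<- cnt + 1; callback(g) }
      NULL
    }
    cpp_generate(n, b$min_edges, b$max_edges, max_degree,
                 stats = FALSE, collect = FALSE, callback = cb)
    return(cnt)
  }
  r <- cpp_generate(n, b$min_edges, b$max_edges, max_degree,
                    stats = FALSE, collect = TRUE, collect_cap = collect_cap)
  out <- lapply(r$graphs, function(e) simple_graph_from_engine(n, e))
  Filter(keep, out)
}

# engine already emits sorted, validated edges: skip re-normalisation
simple_graph_from_engine <- function(n, edges) {
  structure(list(n = as.integer(n), edges = edges,
                 degree = tabulate(edges, nbins = n)),
            class = "simple_graph")
}

#' Count skeletons and summarise their flower-colour subgroups
#'
#' Runs stage 1 in counting mode and, for every emitted skeleton, computes
#' the flowers, the flower colouring and the order of the colour-respecting
#' subgroup N.  No graphs are stored.  Used to characterise how much
#' symmetry the `Aut(G) = NM` factorisation leaves for explicit testing.
#'
#' @param f a `mol_formula` (or formula string).
#' @return list with `graphs` (skeleton count), `n_trivial_N`,
#'   `pct_trivial_N` and `max_N`.
#' @export
stage1_statistics <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  b <- edge_budget(f)
  if (!b$feasible)
    return(list(graphs = 0, n_trivial_N = 0, pct_trivial_N = NA_real_,
                max_N = NA_real_))
  r <- cpp_generate(f$n, b$min_edges, b$max_edges, b$max_degree,
                    stats = TRUE, collect = FALSE)
  list(graphs = r$count,
       n_trivial_N = r$n_trivial_N,
       pct_trivial_N = 100 * r$n_trivial_N / r$count,
       max_N = r$max_N)
}

#' Is this labelled graph the emitted class representative?
#'
#' The generator emits one specific labelled graph per isomorphism class:
#' the one whose every vertex-deletion prefix passes the canonical parent
#' rule and whose attachment sets come first in enumeration order.  This
#' predicate re-checks that construction chain, so exactly one labelled
#' graph per class returns TRUE.
#'
#' @param g a connected [simple_graph()].
#' @return logical.
#' @export
is_canonical_member <- function(g) {
  stopifnot(inherits(g, "simple_graph"))
  if (!is_connected_graph(g)) stop("g must be connected")
  cpp_is_canonical_member(g$n, g$edges)
}

# canonical key usable as a hash for isomorphism classes (uncoloured)
canon_key <- function(g, colors = NULL) {
  paste(cpp_canon_key(g$n, g$edges, colors), collapse = ",")
}
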