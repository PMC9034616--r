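#' Automorphism group of a (possibly vertex-coloured) graph
#'
#' Returns the full colour-preserving automorphism group as an explicit set
#' of permutations.  Groups met during generation are small (rarely above a
#' few thousand), so explicit storage is practical; `cap` guards against
#' degenerate inputs.
#'
#' @param g a [simple_graph()].
#' @param vertex_colors optional integer vector, one colour per vertex;
#'   automorphisms must preserve colours.
#' @param cap maximum group order before aborting with an error.
#' @return an object of class `perm_group`: list with `order` and `members`,
#'   a list of one-line permutations (`p[v]` = image of vertex `v`).
#' @examples
#' cyc5 <- simple_graph(5, cbind(1:5, c(2:5, 1)))
#' automorphism_group(cyc5)$order                      # 10
#' automorphism_group(cyc5, c(2, 1, 1, 1, 1))$order    # 2 (furan colouring)
#' @export
automorphism_group <- function(g, vertex_colors = NULL, cap = 1e6) {
  stopifnot(inherits(g, "simple_graph"))
  if (!is.null(vertex_colors)) {
    stopifnot(length(vertex_colors) == g$n)
    vertex_colors <- as.integer(vertex_colors)
  }
  r <- cpp_aut_group(g$n, g$edges, vertex_colors, cap = cap, members = TRUE)
  structure(list(order = r$order, members = r$members), class = "perm_group")
}

#' @export
print.perm_group <- function(x, ...) {
  cat("perm_group of order", x$order, "\n")
  invisible(x)
}

#' Flowers of a graph
#'
#' A *flower* is a maximal set of leaves (degree-1 vertices) sharing one
#' neighbour; singleton flowers are allowed.  The minor subgroup M of the
#' automorphism group -- generated by transpositions of two leaves within a
#' flower -- has order equal to the product of the factorials of the flower
#' sizes.  In the degenerate two-vertex graph each vertex is a leaf whose
#' neighbour is the other leaf; the two vertices form two singleton flowers
#' and no minor automorphism arises.
#'
#' @param g a [simple_graph()].
#' @return an object of class `flower_partition`: list with `flowers` (list
#'   of increasing integer vectors), `centers` (the common neighbour of each
#'   flower) and `minor_order`.
#' @examples
#' star <- simple_graph(4, cbind(1:3, 4))
#' find_flowers(star)    # one flower {1,2,3}, minor order 3! = 6
#' @export
find_flowers <- function(g) {
  stopifnot(inherits(g, "simple_graph"))
  leaves <- which(g$degree == 1L)
  flowers <- list(); centers <- integer()
  if (length(leaves)) {
    a <- adj_list(g)
    ctr <- vapply(leaves, function(v) a[[v]][1L], integer(1))
    for (c0 in sort(unique(ctr))) {
      flowers[[length(flowers) + 1L]] <- sort(leaves[ctr == c0])
      centers <- c(centers, c0)
    }
  }
  mo <- prod(vapply(flowers, function(fl) factorial(length(fl)), numeric(1)))
  structure(list(flowers = flowers, centers = centers, minor_order = mo),
            class = "flower_partition")
}

#' @export
print.flower_partition <- function(x, ...) {
  cat("flower_partition:", length(x$flowers), "flower(s), minor order",
      x$minor_order, "\n")
  for (i in seq_along(x$flowers))
    cat("  {", paste(x$flowers[[i]], collapse = ","), "} at vertex ",
        x$centers[i], "\n", sep = "")
  invisible(x)
}

#' Flower colouring
#'
#' The vertex colouring used to compute the subgroup N: vertices not in any
#' flower receive the reserved colour 0; within each flower the i-th
#' lowest-numbered vertex receives colour i.  Automorphisms preserving this
#' colouring cannot permute leaves within a flower, but may still exchange
#' whole flowers of equal size or move the graph's non-leaf part.
#'
#' @param g a [simple_graph()].
#' @param fp its [find_flowers()] partition.
#' @return integer vector of colours, length `g$n`.
#' @export
flower_coloring <- function(g, fp = find_flowers(g)) {
  stopifnot(inherits(g, "simple_graph"), inherits(fp, "flower_partition"))
  col <- integer(g$n)
  for (fl in fp$flowers) col[fl] <- seq_along(fl)
  col
}

#' The colour-respecting subgroup N
#'
#' N is the group of automorphisms respecting the flower colouring.  Every
#' automorphism factorises uniquely as an element of N followed by an element
#' of the minor subgroup M, so `|Aut(G)| = |N| * minor_order`; N is a
#' complete set of coset representatives of the normal subgroup M.
#'
#' @inheritParams flower_coloring
#' @param cap passed to [automorphism_group()].
#' @return a `perm_group`.
#' @examples
#' p3 <- simple_graph(3, cbind(1:2, 2:3))
#' compute_N(p3)$order                     # 1; |Aut| = 2 = 1 * 2!
#' @export
compute_N <- function(g, fp = find_flowers(g), cap = 1e6) {
  automorphism_group(g, flower_coloring(g, fp), cap = cap)
}

#' Action of a permutation on a label list
#'
#' The image list assigns to vertex `p[v]` the label that `L` assigns to
#' `v`: `act_on_list(p, L)[p] == L`.
#'
#' @param p one-line permutation (integer vector, `p[v]` = image of `v`).
#' @param L vector of labels, same length.
#' @return the permuted label vector.
#' @examples
#' p <- c(2, 3, 1, 4, 6, 5, 7, 8, 9, 10)            # (1 2 3)(5 6)
#' L <- c("C", "C", "O", "S", "O", "C", "C", "C", "C", "C")
#' act_on_list(p, L)    # (O,C,C,S,C,O,C,C,C,C)
#' @export
act_on_list <- function(p, L) {
  if (length(p) != length(L)) stop("permutation and list lengths differ")
  out <- L
  out[p] <- L
  out
}

# lexicographic comparison of two rank vectors: -1, 0, or 1
lex_cmp <- function(a, b) {
  d <- a - b
  i <- which(d != 0L)
  if (!length(i)) return(0L)
  if (d[i[1L]] > 0L) 1L else -1L
}

#' Class-maximum test for a label list
#'
#' A label list is the representative of its equivalence class under the
#' skeleton's automorphism group when it is the lexicographic maximum of the
#' class (labels compared in a fixed ascending element order).  By the
#' `Aut(G) = NM` factorisation this holds if and only if (a) within each
#' flower the labels are in non-increasing order by vertex number -- which
#' disposes of the minor subgroup M without enumerating it -- and (b) no
#' member of N maps the list to a lexicographically larger one.
#'
#' @param L character vector of labels (one per vertex).
#' @param N the `perm_group` from [compute_N()].
#' @param fp the `flower_partition` of the graph.
#' @param label_order character vector giving the ascending total order of
#'   the labels; defaults to alphabetical order of the labels present.
#' @return TRUE iff `L` is the class maximum.
#' @export
is_class_maximum <- function(L, N, fp, label_order = sort(unique(L))) {
  r <- match(L, label_order)
  if (anyNA(r)) stop("labels outside label_order")
  for (fl in fp$flowers) {
    if (length(fl) > 1L && any(diff(r[fl]) > 0L)) return(FALSE)
  }
  for (p in N$members) {
    if (lex_cmp(act_on_list(p, r), r) > 0L) return(FALSE)
  }
  TRUE
}
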