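#' Element-preserving subgroup acting on edges
#'
#' Filters the stage-2 subgroup N, keeping the members that preserve the
#' element list, and converts each survivor to its induced permutation of
#' the skeleton's fixed edge order.  The subgroup for the bond stage is
#' always obtained this way -- never recomputed from scratch -- mirroring
#' how the element stage's group already contains all the symmetry left.
#'
#' @param N `perm_group` from [compute_N()] for the skeleton.
#' @param L character vector of elements emitted by [assign_elements()].
#' @param g the [simple_graph()].
#' @return a `perm_group` acting on edge positions `1..m`.
#' @export
edge_preserving_subgroup <- function(N, L, g) {
  stopifnot(inherits(g, "simple_graph"))
  m <- nrow(g$edges)
  idx <- edge_index_map(g)
  keep <- Filter(function(p) all(act_on_list(p, L) == L), N$members)
  members <- lapply(keep, function(p) {
    a <- p[g$edges[, 1L]]; b <- p[g$edges[, 2L]]
    ep <- unname(idx[as.character(edge_key(a, b, g$n))])
    if (anyNA(ep)) stop("permutation does not preserve the edge set")
    as.integer(ep)
  })
  structure(list(order = length(members), members = members),
            class = "perm_group")
}

#' Edge flowers
#'
#' The minor subgroup of the element-preserving automorphisms swaps leaves
#' only within a flower and only when they carry the same element; acting on
#' edges, it swaps the corresponding leaf--centre edges.  Each edge flower is
#' therefore the set of edges joining a flower's centre to its same-element
#' leaves; singleton edge flowers are allowed.
#'
#' @param g the [simple_graph()].
#' @param L element list.
#' @param fp [find_flowers()] partition.
#' @return list of increasing integer vectors of edge indices.
#' @export
edge_flowers <- function(g, L, fp = find_flowers(g)) {
  idx <- edge_index_map(g)
  out <- list()
  for (i in seq_along(fp$flowers)) {
    fl <- fp$flowers[[i]]; c0 <- fp$centers[i]
    for (e in unique(L[fl])) {
      mem <- fl[L[fl] == e]
      out[[length(out) + 1L]] <-
        sort(unname(idx[as.character(edge_key(mem, c0, g$n))]))
    }
  }
  out
}

#' Assign bond multiplicities
#'
#' Stage 3: assigns a multiplicity in `{1, 2, 3}` to every skeleton edge,
#' one assignment per orbit of the element-preserving automorphisms.  The
#' orbit representative is the lexicographically maximum multiplicity list
#' over the fixed edge order (so double and triple bonds pack toward
#' low-numbered edges within an orbit), recognised exactly as in stage 2:
#' non-increasing multiplicities within each edge flower plus a scan of the
#' filtered subgroup.
#'
#' Constraints: the incident multiplicity sum at each atom may not exceed
#' its valence, and the total of (valence - incident bonds) over all atoms
#' must equal the hydrogen count -- equivalently the multiplicities sum to
#' the formula's bond total.  Once they hold, hydrogens attach in exactly
#' one way; the per-vertex implicit hydrogen counts are returned with each
#' molecule.  Recursion over edges prunes on the reachable multiplicity
#' total and on per-vertex residual valence.
#'
#' @param g the [simple_graph()].
#' @param L element list from [assign_elements()].
#' @param f the `mol_formula`.
#' @param edgeN `perm_group` on edges from [edge_preserving_subgroup()].
#' @param efp edge flowers from [edge_flowers()].
#' @param callback optional function receiving each `molecule`; when given,
#'   molecules are not accumulated and a count is returned.
#' @return list of `molecule` objects (or a count).
#' @export
assign_multiplicities <- function(g, L, f, edgeN = NULL, efp = NULL,
                                  callback = NULL) {
  stopifnot(inherits(g, "simple_graph"), inherits(f, "mol_formula"))
  b <- edge_budget(f)
  if (!b$feasible) return(if (is.null(callback)) list() else 0)
  if (is.null(efp)) efp <- edge_flowers(g, L)
  if (is.null(edgeN)) edgeN <- edge_preserving_subgroup(compute_N(g), L, g)

  m <- nrow(g$edges)
  val <- unname(f$valences[L])
  if (m == 0L) {
    # single-vertex molecule: hydrogens must exactly fill the valence
    if (g$n == 1L && val[1L] == f$hydrogens) {
      mol <- new_molecule(g, L, integer(0), f)
      if (is.null(callback)) return(list(mol))
      callback(mol); return(1)
    }
    return(if (is.null(callback)) list() else 0)
  }

  target <- b$bond_total
  res <- val - g$degree                 # residual valence beyond single bonds
  if (any(res < 0L)) return(if (is.null(callback)) list() else 0)

  prev_in_flower <- integer(m)
  for (fl in efp) {
    if (length(fl) > 1L) prev_in_flower[fl[-1L]] <- fl[-length(fl)]
  }
  nontriv <- Filter(function(p) any(p != seq_len(m)), edgeN$members)

  # inc and tot count every unassigned edge as a single bond; assigning
  # multiplicity k to an edge adds the k-1 extra
  inc <- g$degree
  mult <- integer(m)
  tot <- 0L
  out <- list()
  count <- 0

  emit_mol <- function() {
    for (p in nontriv) {
      if (lex_cmp(mult[order(p)], mult) > 0L) return(invisible())
    }
    mol <- new_molecule(g, L, mult, f)
    if (is.null(callback)) out[[length(out) + 1L]] <<- mol else callback(mol)
    count <<- count + 1
  }

  rec <- function(i) {
    if (i > m) {
      if (tot == target) emit_mol()
      return(invisible())
    }
    a <- g$edges[i, 1L]; bb <- g$edges[i, 2L]
    rem <- m - i
    hi <- min(3L,
              val[a] - inc[a] + 1L,     # +1: this edge already counted once
              val[bb] - inc[bb] + 1L,
              target - tot + 1L)
    if (prev_in_flower[i] > 0L)
      hi <- min(hi, mult[prev_in_flower[i]])
    lo <- max(1L, target - tot + 1L - 2L * rem)  # later edges grow by <= 2 each
    if (hi < lo) return(invisible())
    for (k in lo:hi) {
      extra <- k - 1L
      inc[a] <<- inc[a] + extra; inc[bb] <<- inc[bb] + extra
      tot <<- tot + extra
      mult[i] <<- k
      rec(i + 1L)
      inc[a] <<- inc[a] - extra; inc[bb] <<- inc[bb] - extra
      tot <<- tot - extra
    }
    invisible()
  }
  tot <- m                              # all edges start as single bonds
  rec(1L)
  if (is.null(callback)) out else count
}

#' Completed molecule
#'
#' A hydrogen-suppressed multigraph: skeleton, element per vertex, bond
#' multiplicity per edge, plus the implied per-vertex hydrogen counts.
#'
#' @param g skeleton.
#' @param elements character vector, one element per vertex.
#' @param bonds integer multiplicities over the skeleton's edge order.
#' @param f the `mol_formula` (for valences).
#' @return an object of class `molecule`.
#' @keywords internal
new_molecule <- function(g, elements, bonds, f) {
  val <- unname(f$valences[elements])
  inc <- integer(g$n)
  for (i in seq_len(nrow(g$edges))) {
    inc[g$edges[i, 1L]] <- inc[g$edges[i, 1L]] + bonds[i]
    inc[g$edges[i, 2L]] <- inc[g$edges[i, 2L]] + bonds[i]
  }
  ih <- val - inc
  if (any(ih < 0L)) stop("valence exceeded")
  structure(list(graph = g, elements = elements, bonds = as.integer(bonds),
                 implicit_h = ih),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("molecule:", write_smiles(x), "\n")
  invisible(x)
}
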