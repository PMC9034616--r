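#' Brute-force reference enumerator
#'
#' Independent oracle used to validate the pipeline on small formulas: it
#' enumerates every labelled simple graph on the heavy atoms, every element
#' labelling and every bond-multiplicity vector, keeps the connected,
#' valence-feasible, hydrogen-exact and filter-passing structures, and
#' deduplicates them by an exhaustive canonical form (the minimum encoding
#' over all vertex permutations).  Nothing is shared with the generation
#' path: no canonical augmentation, no automorphism groups, no orbit
#' representatives.
#'
#' Complexity is factorial; the size guard (at most 7 heavy atoms and 12
#' hydrogens) keeps it within test-suite scale.
#'
#' @param f a `mol_formula` or formula string.
#' @param filters a [filter_config()].
#' @return list with `count` and `representatives` (character vector of
#'   canonical encodings).
#' @examples
#' brute_force_count("C2H6O")$count   # 2
#' @export
brute_force_count <- function(f, filters = filter_config()) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "mol_formula"))
  if (f$n > 7L || f$hydrogens > 12L)
    stop("brute-force oracle is guarded to n <= 7 and h <= 12")
  b <- edge_budget(f)
  if (!b$feasible) return(list(count = 0, representatives = character()))
  n <- f$n
  syms <- names(f$counts)
  val <- f$valences
  target <- b$bond_total
  want_b5 <- 5L %in% filters$badlists

  pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(integer(), 0L, 2L)
  npairs <- nrow(pairs)
  perms <- all_permutations(n)

  reps <- new.env(parent = emptyenv())

  labelings <- multiset_permutations(rep(syms, f$counts))

  consider_graph <- function(sel) {
    edges <- pairs[sel, , drop = FALSE]
    g <- simple_graph(n, edges)
    if (any(g$degree > max(val))) return(invisible())
    if (!is_connected_graph(g)) return(invisible())
    if (!is.null(filters$pentagon_bounds)) {
      p5 <- count_cycles(g, 5L)
      if (p5 < filters$pentagon_bounds[1L] ||
          p5 > filters$pentagon_bounds[2L]) return(invisible())
    }
    if (filters$planar_only && !is_planar(g)) return(invisible())
    if (9L %in% filters$badlists && !passes_B9(g)) return(invisible())
    m <- nrow(edges)
    for (lab in labelings) {
      if (any(val[lab] < g$degree)) next
      for (mv in multiplicity_vectors(m, target)) {
        inc <- integer(n)
        for (i in seq_len(m)) {
          inc[edges[i, 1L]] <- inc[edges[i, 1L]] + mv[i]
          inc[edges[i, 2L]] <- inc[edges[i, 2L]] + mv[i]
        }
        if (any(inc > val[lab])) next
        mol <- new_molecule(g, lab, mv, f)
        if (want_b5 && !passes_B5(mol)) next
        key <- oracle_canonical_form(n, edges, mv, lab, perms)
        assign(key, TRUE, envir = reps)
      }
    }
    invisible()
  }

  if (n == 1L) {
    if (val[[syms[1L]]] == f$hydrogens)
      assign(paste0(syms[1L], ";"), TRUE, envir = reps)
  } else {
    for (m in b$min_edges:b$max_edges) {
      if (m == 0L) { consider_graph(integer()) ; next }
      sets <- utils::combn(npairs, m)
      for (j in seq_len(ncol(sets))) consider_graph(sets[, j])
    }
  }
  keys <- ls(reps)
  list(count = length(keys), representatives = sort(keys))
}

# minimum over all vertex permutations of the (elements; multi-adjacency)
# string encoding
oracle_canonical_form <- function(n, edges, mult, lab, perms) {
  m <- nrow(edges)
  best <- NULL
  for (p in perms) {
    a <- p[edges[, 1L]]; b <- p[edges[, 2L]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    o <- order(lo, hi)
    enc <- paste0(paste(lab[order(p)], collapse = ","), ";",
                  paste(lo[o], hi[o], mult[o], sep = "-", collapse = " "))
    if (is.null(best) || enc < best) best <- enc
  }
  best
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  rec <- function(cur, rest) {
    if (!length(rest)) { out[[length(out) + 1L]] <<- cur; return(invisible()) }
    for (i in seq_along(rest)) rec(c(cur, rest[i]), rest[-i])
  }
  rec(integer(), seq_len(n))
  out
}

# distinct orderings of a multiset of symbols
multiset_permutations <- function(x) {
  out <- list()
  counts <- table(x)
  syms <- names(counts)
  n <- length(x)
  cur <- character(n)
  rec <- function(pos, counts) {
    if (pos > n) { out[[length(out) + 1L]] <<- cur; return(invisible()) }
    for (s in syms) {
      if (counts[[s]] > 0L) {
        counts2 <- counts; counts2[[s]] <- counts2[[s]] - 1L
        cur[pos] <<- s
        rec(pos + 1L, counts2)
      }
    }
    invisible()
  }
  rec(1L, as.list(counts))
  out
}

# all vectors in {1,2,3}^m with the given sum
multiplicity_vectors <- function(m, total) {
  if (m == 0L) return(if (total == 0L) list(integer()) else list())
  out <- list()
  cur <- integer(m)
  rec <- function(i, left) {
    rem <- m - i + 1L
    if (left < rem || left > 3L * rem) return(invisible())
    if (i > m) { if (left == 0L) out[[length(out) + 1L]] <<- cur
                 return(invisible()) }
    for (k in 1L:3L) {
      cur[i] <<- k
      rec(i + 1L, left - k)
    }
    invisible()
  }
  rec(1L, total)
  out
}
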