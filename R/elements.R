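#' Assign element symbols to skeleton vertices
#'
#' Stage 2 of the pipeline: produces every assignment of the formula's
#' element symbols to the vertices of a skeleton, exactly one per orbit of
#' the skeleton's automorphism group.  The representative of each orbit is
#' the lexicographically maximum list (elements compared in their fixed
#' ascending alphabetical order).  Vertices are filled in order of vertex
#' number; the flower inequalities (labels non-increasing within a flower)
#' are enforced as soon as they become active, and a completed list is kept
#' only if no member of N maps it to a larger list.
#'
#' Each emitted list satisfies `valence(element(v)) >= degree(v)` at every
#' vertex, since implicit hydrogens cannot be negative.
#'
#' @param g a [simple_graph()].
#' @param f the `mol_formula`; its counts must total `g$n`.
#' @param N the subgroup from [compute_N()]; computed if missing.
#' @param fp the [find_flowers()] partition; computed if missing.
#' @param use_orbit_shortcut if TRUE, additionally prune with the inequality
#'   `element(u) >= element(w)` for each member of N, where `u` is the least
#'   vertex that member moves and `w` its pre-image.  This is pure pruning:
#'   the emitted set is unchanged.
#' @param callback optional function invoked with each list; when supplied,
#'   lists are not accumulated and the count is returned.
#' @return a list of character vectors (or a count when `callback` is given).
#' @examples
#' cyc5 <- simple_graph(5, cbind(1:5, c(2:5, 1)))
#' f <- parse_formula("C4H4O")
#' length(assign_elements(cyc5, f))   # 1: unique oxygen placement in a 5-ring
#' @export
assign_elements <- function(g, f, N = NULL, fp = NULL,
                            use_orbit_shortcut = FALSE, callback = NULL) {
  stopifnot(inherits(g, "simple_graph"), inherits(f, "mol_formula"))
  if (sum(f$counts) != g$n)
    stop("formula heavy-atom count does not match vertex count")
  if (is.null(fp)) fp <- find_flowers(g)
  if (is.null(N)) N <- compute_N(g, fp)

  syms <- names(f$counts)                    # ascending fixed order
  nsym <- length(syms)
  remaining <- as.integer(f$counts)
  val <- as.integer(f$valences)
  deg <- g$degree
  n <- g$n

  # previous vertex in the same flower (0 if none): activates the inequality
  prev_in_flower <- integer(n)
  for (fl in fp$flowers) {
    if (length(fl) > 1L)
      prev_in_flower[fl[-1L]] <- fl[-length(fl)]
  }

  # non-identity members of N, as rank permutations; orbit-shortcut pairs
  nontriv <- Filter(function(p) any(p != seq_len(n)), N$members)
  shortcut_pairs <- NULL
  if (use_orbit_shortcut && length(nontriv)) {
    sp <- lapply(nontriv, function(p) {
      u <- which(p != seq_len(n))[1L]     # least moved vertex
      w <- which(p == u)                  # pre-image of u
      c(u, w)
    })
    sp <- unique(sp)
    shortcut_pairs <- sp[vapply(sp, function(x) x[2L] > x[1L], logical(1))]
  }

  out <- list()
  count <- 0
  L <- integer(n)                         # element ranks, 1..nsym

  emit_list <- function() {
    for (p in nontriv) {
      if (lex_cmp(L[order(p)], L) > 0L) return(invisible())
      # L[order(p)] == act_on_list(p, L): position p[v] gets L[v]
    }
    labs <- syms[L]
    if (is.null(callback)) {
      out[[length(out) + 1L]] <<- labs
    } else {
      callback(labs)
    }
    count <<- count + 1
  }

  rec <- function(v) {
    if (v > n) { emit_list(); return(invisible()) }
    hi <- nsym
    pv <- prev_in_flower[v]
    if (pv > 0L) hi <- L[pv]              # non-increasing within the flower
    for (e in seq_len(min(hi, nsym))) {
      if (remaining[e] == 0L) next
      if (val[e] < deg[v]) next
      if (!is.null(shortcut_pairs)) {
        ok <- TRUE
        for (uw in shortcut_pairs)
          if (uw[2L] == v && L[uw[1L]] < e) { ok <- FALSE; break }
        if (!ok) next
      }
      remaining[e] <<- remaining[e] - 1L
      L[v] <<- e
      rec(v + 1L)
      remaining[e] <<- remaining[e] + 1L
    }
    invisible()
  }
  rec(1L)
  if (is.null(callback)) out else count
}
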