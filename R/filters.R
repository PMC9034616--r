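#' Structural filter configuration
#'
#' Filters are applied at the earliest stage at which they are decidable:
#' 5-ring count bounds, planarity and badlist 9 depend only on the skeleton
#' and prune at stage 1; badlist 5 needs bond multiplicities and prunes at
#' stage 3.
#'
#' @param pentagon_bounds optional `c(min, max)` bounds on the number of
#'   5-cycles of the skeleton.
#' @param planar_only if TRUE, keep only planar skeletons.
#' @param badlists integer vector, subset of `c(5, 9)`:
#'   badlist 5 rejects molecules in which some atom has two double bonds and
#'   otherwise only hydrogen neighbours (cumulated systems such as O=C=O);
#'   badlist 9 rejects skeletons in which some atom lies on more than one
#'   cycle of length 3 or 4.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(pentagon_bounds = NULL, planar_only = FALSE,
                          badlists = integer()) {
  if (!is.null(pentagon_bounds)) {
    pentagon_bounds <- as.integer(pentagon_bounds)
    if (length(pentagon_bounds) != 2L || anyNA(pentagon_bounds) ||
        pentagon_bounds[1L] > pentagon_bounds[2L] || pentagon_bounds[1L] < 0L)
      stop("pentagon_bounds must be c(min, max) with 0 <= min <= max")
  }
  badlists <- as.integer(badlists)
  if (length(setdiff(badlists, c(5L, 9L))))
    stop("unknown badlist number(s): ",
         paste(setdiff(badlists, c(5L, 9L)), collapse = ", "),
         " (available: 5, 9)")
  structure(list(pentagon_bounds = pentagon_bounds,
                 planar_only = isTRUE(planar_only),
                 badlists = sort(unique(badlists))),
            class = "filter_config")
}

is_null_filter <- function(fc) {
  is.null(fc$pentagon_bounds) && !fc$planar_only && !length(fc$badlists)
}

# enumerate simple cycles of exactly `length` vertices; returns a list of
# increasing vertex vectors (each cycle once)
enumerate_cycles <- function(g, length) {
  stopifnot(length >= 3L, length <= g$n)
  a <- adj_list(g)
  cycles <- list()
  path <- integer(length)
  # cycles are rooted at their smallest vertex; the two traversal directions
  # are deduplicated by requiring the second vertex below the last one
  rec <- function(v, depth, s) {
    for (u in a[[v]]) {
      if (depth == length) {
        if (u == s && path[2L] < path[length]) {
          cycles[[base::length(cycles) + 1L]] <<- sort(path)
        }
      } else if (u > s && !(u %in% path[seq_len(depth)])) {
        path[depth + 1L] <<- u
        rec(u, depth + 1L, s)
      }
    }
    invisible()
  }
  for (s in seq_len(g$n)) {
    path[1L] <- s
    rec(s, 1L, s)
  }
  cycles
}

#' Count simple cycles of a given length
#'
#' Cycles are counted as vertex sets traversed, not as directed traversals;
#' exhaustive enumeration, intended for short rings at generation sizes.
#'
#' @param g a [simple_graph()].
#' @param length cycle length, between 3 and `g$n`.
#' @return integer count.
#' @examples
#' count_cycles(simple_graph(4, cbind(c(1,1,1,2,2,3), c(2,3,4,3,4,4))), 3) # K4: 4
#' @export
count_cycles <- function(g, length) {
  if (length > g$n) return(0L)
  base::length(enumerate_cycles(g, length))
}

#' Badlist 9: fused or spiro small rings
#'
#' TRUE iff no vertex belongs to two or more distinct cycles of length 3 or
#' 4 (cycles distinct as vertex sets; one 3-cycle plus one 4-cycle through
#' the same atom also fails).
#'
#' @param g a [simple_graph()].
#' @return logical.
#' @export
passes_B9 <- function(g) {
  hits <- integer(g$n)
  for (len in c(3L, 4L)) {
    if (len > g$n) next
    for (cy in enumerate_cycles(g, len)) hits[cy] <- hits[cy] + 1L
  }
  all(hits <= 1L)
}

#' Badlist 5: cumulated double bonds with only hydrogen neighbours
#'
#' TRUE iff no atom simultaneously has exactly two incident double bonds and
#' no non-hydrogen neighbour besides the two doubly-bonded partners.  An
#' atom whose remaining valence is empty or pure hydrogen fails the
#' neighbour condition vacuously, so central atoms of cumulated systems such
#' as H2C=C=CH2 or O=C=O are rejected.
#'
#' @param m a `molecule`.
#' @return logical.
#' @export
passes_B5 <- function(m) {
  g <- m$graph
  doubles <- integer(g$n)
  for (i in seq_len(nrow(g$edges))) {
    if (m$bonds[i] == 2L) {
      doubles[g$edges[i, 1L]] <- doubles[g$edges[i, 1L]] + 1L
      doubles[g$edges[i, 2L]] <- doubles[g$edges[i, 2L]] + 1L
    }
  }
  # an atom with two doubles and any further heavy neighbour (single or
  # triple) passes; with degree 2 its only neighbours are the double partners
  !any(doubles == 2L & g$degree == 2L)
}

#' Planarity test
#'
#' A skeleton with cycle rank `m - n + c <= 3` is always planar (the
#' Kuratowski graphs have cycle rank 4 and 6, and the rank of a subgraph
#' never exceeds that of the host), which settles nearly every molecular
#' skeleton instantly.  Richer graphs are tested exactly by
#' Demoucron-Malgrange-Pertuiset face embedding, run per biconnected
#' component.
#'
#' @param g a [simple_graph()].
#' @return logical.
#' @examples
#' is_planar(simple_graph(4, cbind(1:3, 2:4)))   # a path: TRUE
#' @export
is_planar <- function(g) {
  n <- g$n; m <- nrow(g$edges)
  comp <- igraph::components(as_igraph(g))$no
  if (m - n + comp <= 3L) return(TRUE)
  bc <- igraph::biconnected_components(as_igraph(g))
  for (vs in bc$components) {
    verts <- sort(as.integer(vs))
    if (length(verts) < 5L) next
    sel <- g$edges[, 1L] %in% verts & g$edges[, 2L] %in% verts
    sub <- matrix(match(g$edges[sel, , drop = FALSE], verts),
                  ncol = 2L)
    nb <- length(verts); mb <- nrow(sub)
    if (mb - nb + 1L <= 3L) next
    if (mb > 3L * nb - 6L) return(FALSE)
    if (!demoucron_planar(nb, sub)) return(FALSE)
  }
  TRUE
}

# exact planarity of a 2-connected graph by iterative face embedding:
# repeatedly place a path of some bridge (fragment) into an admissible face;
# fail when a fragment has no admissible face.  Choosing any fragment with a
# unique admissible face first keeps the greedy procedure exact.
demoucron_planar <- function(n, edges) {
  a <- rep(list(integer()), n)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    a[[u]] <- c(a[[u]], v); a[[v]] <- c(a[[v]], u)
  }
  ek <- function(u, v) paste(pmin(u, v), pmax(u, v))
  all_edges <- ek(edges[, 1L], edges[, 2L])

  # initial cycle via DFS back edge
  parent <- rep(NA_integer_, n)
  stack <- 1L; seen <- logical(n); seen[1L] <- TRUE
  cyc <- NULL
  dfs_find <- function(v) {
    for (u in a[[v]]) {
      if (!seen[u]) {
        seen[u] <<- TRUE; parent[u] <<- v
        dfs_find(u)
      } else if (!identical(u, parent[v]) && is.null(cyc)) {
        # back edge v-u closes a cycle (only need one)
        p <- v; walk <- v
        while (!is.na(parent[p]) && p != u) { p <- parent[p]; walk <- c(walk, p) }
        if (p == u) cyc <<- walk
      }
      if (!is.null(cyc)) return(invisible())
    }
    invisible()
  }
  dfs_find(1L)
  if (is.null(cyc)) return(TRUE)     # acyclic: planar

  in_H <- logical(n); in_H[cyc] <- TRUE
  emb <- ek(cyc, c(cyc[-1L], cyc[1L]))
  faces <- list(cyc, cyc)            # the cycle bounds two faces

  repeat {
    todo <- setdiff(all_edges, emb)
    if (!length(todo)) return(TRUE)

    # fragments: chords between embedded vertices, and components of the
    # unembedded vertices with their attachment edges
    frags <- list()
    for (e in todo) {
      uv <- as.integer(strsplit(e, " ")[[1L]])
      if (in_H[uv[1L]] && in_H[uv[2L]])
        frags[[length(frags) + 1L]] <- list(att = uv, comp = integer())
    }
    outv <- which(!in_H)
    if (length(outv)) {
      cid <- rep(0L, n); cur <- 0L
      for (s in outv) {
        if (cid[s]) next
        cur <- cur + 1L
        q <- s; cid[s] <- cur
        while (length(q)) {
          v <- q[1L]; q <- q[-1L]
          for (u in a[[v]]) if (!in_H[u] && !cid[u]) { cid[u] <- cur; q <- c(q, u) }
        }
      }
      for (k in seq_len(cur)) {
        comp <- which(cid == k)
        att <- sort(unique(unlist(lapply(comp, function(v) a[[v]][in_H[a[[v]]]]))))
        frags[[length(frags) + 1L]] <- list(att = att, comp = comp)
      }
    }

    adm <- lapply(frags, function(fr)
      which(vapply(faces, function(fc) all(fr$att %in% fc), logical(1))))
    nadm <- lengths(adm)
    if (any(nadm == 0L)) return(FALSE)
    pick <- if (any(nadm == 1L)) which(nadm == 1L)[1L] else 1L
    fr <- frags[[pick]]
    face_i <- adm[[pick]][1L]

    # an alpha path: between two distinct attachments, interior outside H
    if (length(fr$comp) == 0L) {
      pth <- fr$att                     # a chord
    } else {
      s <- fr$att[1L]; t <- fr$att[2L]
      prev <- rep(NA_integer_, n)
      q <- s; vis <- logical(n); vis[s] <- TRUE
      while (length(q)) {
        v <- q[1L]; q <- q[-1L]
        if (v == t) break
        for (u in a[[v]]) {
          if (vis[u]) next
          # only fragment edges: interior steps stay in the component, and t
          # may be entered from the component only (never along an H-H edge)
          if (u %in% fr$comp || (u == t && v %in% fr$comp)) {
            vis[u] <- TRUE; prev[u] <- v; q <- c(q, u)
          }
        }
      }
      pth <- t
      while (pth[1L] != s) pth <- c(prev[pth[1L]], pth)
    }

    # embed the path, splitting the chosen face into two
    fc <- faces[[face_i]]
    ia <- which(fc == pth[1L])[1L]; ib <- which(fc == pth[length(pth)])[1L]
    if (ia > ib) { tmp <- ia; ia <- ib; ib <- tmp; pth <- rev(pth) }
    interior <- pth[-c(1L, length(pth))]      # ordered fc[ia] -> fc[ib]
    in_H[interior] <- TRUE
    emb <- c(emb, ek(pth[-length(pth)], pth[-1L]))
    arc1 <- fc[ia:ib]                  # fc[ia] .. fc[ib] along the face
    arc2 <- c(fc[ib:length(fc)], fc[seq_len(ia)])  # fc[ib] .. fc[ia] wrapping
    faces[[face_i]] <- c(arc1, rev(interior))
    faces[[length(faces) + 1L]] <- c(arc2, interior)
  }
}
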