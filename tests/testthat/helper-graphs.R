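# shared fixtures and small independent oracles, all built in code

cycle_graph <- function(n) simple_graph(n, cbind(seq_len(n), c(seq_len(n)[-1L], 1L)))
path_graph <- function(n) simple_graph(n, cbind(seq_len(n - 1L), 2:n))
star_graph <- function(k) simple_graph(k + 1L, cbind(seq_len(k), k + 1L))
complete_graph <- function(n) simple_graph(n, t(utils::combn(n, 2L)))

petersen_graph <- function() {
  simple_graph(10, cbind(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                         c(2, 3, 4, 5, 1, 6, 7, 8, 9, 10, 8, 9, 10, 6, 7)))
}

# random connected graph: random attachment tree plus optional extra edges
random_connected_graph <- function(n, extra = 0L) {
  edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L), integer(1)))
  if (extra > 0L) {
    all_p <- t(utils::combn(n, 2L))
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    free <- all_p[!(paste(all_p[, 1L], all_p[, 2L]) %in% key), , drop = FALSE]
    if (nrow(free)) {
      take <- utils::head(sample.int(nrow(free)), extra)
      edges <- rbind(edges, free[take, , drop = FALSE])
    }
  }
  simple_graph(n, edges)
}

ig_of <- function(g) {
  ig <- igraph::make_empty_graph(g$n, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

# BLISS-based group order (independent of the package's own engine)
igraph_aut_order <- function(g, colors = NULL) {
  as.numeric(igraph::count_automorphisms(ig_of(g), colors = colors)$group_size)
}

# planarity oracle through networkx (python is part of the test environment)
networkx_planar <- function(g) {
  el <- paste(sprintf("(%d,%d)", g$edges[, 1L], g$edges[, 2L]), collapse = ",")
  code <- sprintf(paste0(
    "import networkx as nx; g=nx.Graph([%s]); ",
    "g.add_nodes_from(range(1,%d+1)); print(nx.check_planarity(g)[0])"),
    el, g$n)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  identical(out, "True")
}

obabel_canonical <- function(smiles) {
  tf <- tempfile(fileext = ".smi")
  on.exit(unlink(tf))
  writeLines(smiles, tf)
  out <- system2("obabel", c("-ismi", tf, "-ocan"), stdout = TRUE,
                 stderr = FALSE)
  sub("\t.*$", "", trimws(out))
}

obabel_canonical_sdf <- function(sdf_text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_text, tf)
  out <- system2("obabel", c("-isdf", tf, "-ocan"), stdout = TRUE,
                 stderr = FALSE)
  sub("\t.*$", "", trimws(out))
}

# isomorphism-class count of connected simple graphs by exhaustive labelled
# enumeration + permutation-minimal encoding (independent of the generator)
brute_force_graph_classes <- function(n, min_edges, max_edges, max_degree) {
  if (n == 1L) return(if (min_edges <= 0L && max_edges >= 0L) 1L else 0L)
  pairs <- t(utils::combn(n, 2L))
  perms <- isogen:::all_permutations(n)
  seen <- new.env(parent = emptyenv())
  np <- nrow(pairs)
  for (mask in seq_len(2^np) - 1L) {
    sel <- bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0
    m <- sum(sel)
    if (m < min_edges || m > max_edges) next
    g <- simple_graph(n, pairs[sel, , drop = FALSE])
    if (any(g$degree > max_degree)) next
    if (!isogen:::is_connected_graph(g)) next
    best <- NULL
    for (p in perms) {
      a <- p[g$edges[, 1L]]; b <- p[g$edges[, 2L]]
      lo <- pmin(a, b); hi <- pmax(a, b)
      o <- order(lo, hi)
      enc <- paste(lo[o], hi[o], sep = "-", collapse = " ")
      if (is.null(best) || enc < best) best <- enc
    }
    assign(best, TRUE, envir = seen)
  }
  length(ls(seen))
}

# the minor subgroup M as an explicit set: all products of within-flower
# permutations (identity outside the flowers)
minor_subgroup_members <- function(g, fp) {
  out <- list(seq_len(g$n))
  for (fl in fp$flowers) {
    if (length(fl) == 1L) next
    perms_fl <- isogen:::all_permutations(length(fl))
    new_out <- list()
    for (base_p in out) {
      for (q in perms_fl) {
        p <- base_p
        p[fl] <- p[fl[q]]
        new_out[[length(new_out) + 1L]] <- p
      }
    }
    out <- new_out
  }
  out
}

perm_key <- function(p) paste(p, collapse = ",")
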