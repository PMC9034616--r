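# SMILES default-valence table: implicit hydrogens on a bare organic-subset
# atom are inferred from the smallest standard valence not below the bond
# order sum.  Atoms whose hydrogen count under our fixed valences differs
# are written in brackets with an explicit H count.
smiles_standard_valences <- list(B = 3L, C = 4L, N = c(3L, 5L), O = 2L,
                                 P = c(3L, 5L), S = c(2L, 4L, 6L),
                                 F = 1L, Cl = 1L, Br = 1L, I = 1L)

#' Build a SMILES template for a skeleton
#'
#' All molecules sharing a skeleton differ only in atom symbols and bond
#' orders, so the expensive part of SMILES writing -- the spanning-tree
#' walk with ring-closure digits -- is done once per skeleton and reused.
#' The walk starts at vertex 1, visits neighbours in ascending vertex
#' order, assigns ring-closure digits in discovery order, and emits every
#' edge exactly once (as a tree edge or as a closure pair).
#'
#' @param g a connected [simple_graph()].
#' @return an object of class `smiles_template`.
#' @export
build_smiles_template <- function(g) {
  stopifnot(inherits(g, "simple_graph"))
  if (!is_connected_graph(g)) stop("template requires a connected graph")
  n <- g$n
  a <- adj_list(g)
  idx <- edge_index_map(g)
  eid <- function(u, v) unname(idx[as.character(edge_key(u, v, n))])

  used <- logical(nrow(g$edges))       # edge handled (tree or closure)
  visited <- logical(n)
  closure_open <- rep(list(NULL), n)   # per-vertex list of (digit, edge)
  closure_close <- rep(list(NULL), n)
  ndig <- 0L

  # pass 1: classify edges, assign ring digits in DFS discovery order
  children <- rep(list(integer()), n)
  classify <- function(v, parent) {
    visited[v] <<- TRUE
    for (u in a[[v]]) {
      e <- eid(u, v)
      if (used[e]) next
      if (!visited[u]) {
        used[e] <<- TRUE
        children[[v]] <<- c(children[[v]], u)
        classify(u, v)
      } else {
        used[e] <<- TRUE               # back edge: u is an ancestor of v
        ndig <<- ndig + 1L
        closure_open[[u]] <<- c(closure_open[[u]], list(c(ndig, e)))
        closure_close[[v]] <<- c(closure_close[[v]], list(c(ndig, e)))
      }
    }
    invisible()
  }
  classify(1L, 0L)

  # pass 2: emit tokens
  tokens <- list()
  push <- function(t) tokens[[length(tokens) + 1L]] <<- t
  emit <- function(v) {
    push(list(t = "atom", v = v))
    for (cl in closure_open[[v]])
      push(list(t = "ring", d = cl[1L], e = cl[2L], bond = TRUE))
    for (cl in closure_close[[v]])
      push(list(t = "ring", d = cl[1L], e = cl[2L], bond = TRUE))
    ch <- children[[v]]
    for (i in seq_along(ch)) {
      last <- i == length(ch)
      if (!last) push(list(t = "open"))
      push(list(t = "bond", e = eid(v, ch[i])))
      emit(ch[i])
      if (!last) push(list(t = "close"))
    }
    invisible()
  }
  emit(1L)
  structure(list(tokens = tokens, n = n, n_closures = ndig, graph = g),
            class = "smiles_template")
}

#' @export
print.smiles_template <- function(x, ...) {
  cat("smiles_template:", x$n, "atoms,", x$n_closures, "ring closure(s)\n")
  invisible(x)
}

# token renderer: element symbols + bond orders into the template
render_smiles <- function(t, elements, bonds, valences) {
  n <- t$n
  inc <- integer(n)
  g <- t$graph
  for (i in seq_len(nrow(g$edges))) {
    inc[g$edges[i, 1L]] <- inc[g$edges[i, 1L]] + bonds[i]
    inc[g$edges[i, 2L]] <- inc[g$edges[i, 2L]] + bonds[i]
  }
  bond_chr <- c("", "=", "#")
  out <- character(0)
  for (tk in t$tokens) {
    out <- c(out, switch(tk$t,
      atom = {
        sym <- elements[tk$v]
        ourh <- valences[[sym]] - inc[tk$v]
        std <- smiles_standard_valences[[sym]]
        stdh <- if (is.null(std)) -1L else {
          fit <- std[std >= inc[tk$v]]
          if (length(fit)) fit[1L] - inc[tk$v] else 0L
        }
        if (!is.null(std) && stdh == ourh) sym
        else if (ourh == 0L) paste0("[", sym, "]")
        else if (ourh == 1L) paste0("[", sym, "H]")
        else paste0("[", sym, "H", ourh, "]")
      },
      bond = bond_chr[bonds[tk$e]],
      ring = paste0(bond_chr[bonds[tk$e]],
                    if (tk$d > 9L) paste0("%", tk$d) else tk$d),
      open = "(",
      close = ")"
    ))
  }
  paste(out, collapse = "")
}

#' Write a molecule as a SMILES line
#'
#' Atoms appear in template (DFS) order -- the raw generation order, not a
#' canonical SMILES.  Double and triple bonds are written `=` and `#`;
#' hydrogens are implicit wherever the SMILES standard valence of the bare
#' atom reproduces the molecule's hydrogen count, and written as a bracket
#' H-count otherwise.
#'
#' @param m a `molecule`.
#' @param t its skeleton's [build_smiles_template()]; built on the fly if
#'   missing (reuse the template when writing many molecules per skeleton).
#' @param valences named valence table; defaults to the package table.
#' @return a single SMILES string.
#' @examples
#' mol <- generate_isomers("CH4")$molecules[[1]]
#' write_smiles(mol)   # "C"
#' @export
write_smiles <- function(m, t = NULL, valences = default_valences) {
  stopifnot(inherits(m, "molecule"))
  if (is.null(t)) t <- build_smiles_template(m$graph)
  vals <- as.list(valences)
  # molecule knows its implicit h; recover per-atom valence from it
  for (s in unique(m$elements)) {
    if (is.null(vals[[s]])) stop("no valence for element ", s)
  }
  render_smiles(t, m$elements, m$bonds, vals)
}

#' Write a molecule as an SDfile (V2000) block
#'
#' Produces a syntactically valid molfile: counts line, atom block with
#' all-zero coordinates (the generator is constitution-only; no 2D/3D
#' layout is attempted), bond block with orders 1-3, `M  END` and the
#' `$$$$` record separator.
#'
#' @param m a `molecule`.
#' @param index record number used in the title line.
#' @return a character scalar (the molfile block, newline-separated).
#' @export
write_sdf <- function(m, index = 1L) {
  stopifnot(inherits(m, "molecule"))
  g <- m$graph
  na <- g$n; nb <- nrow(g$edges)
  if (na > 999L || nb > 999L)
    stop("V2000 molfiles support at most 999 atoms/bonds")
  lines <- c(
    sprintf("mol%d", as.integer(index)),
    "  isogen 0D",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, m$elements),
    if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                    g$edges[, 1L], g$edges[, 2L], m$bonds),
    "M  END",
    "$$$$")
  paste(lines, collapse = "\n")
}
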