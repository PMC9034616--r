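#' Default valence table
#'
#' One fixed valence per element per run.  Overrides can be supplied to
#' [parse_formula()] or on the command line as `El=val` pairs.
#' @keywords internal
default_valences <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L)

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula such as `"C7H12O2S"` into heavy-atom
#' counts, a hydrogen count and a valence table.  Element tokens are an
#' upper-case letter optionally followed by a lower-case letter, with an
#' optional count (default 1); tokens may repeat and hydrogens may appear
#' anywhere in the string.  Hydrogen is never a graph vertex: it is implied
#' by unused valence.
#'
#' @param text formula string, e.g. `"C9H18N2O4"`.
#' @param valence_overrides optional named integer vector, e.g. `c(S = 6)`,
#'   overriding (or extending) the default valence table
#'   C=4, N=3, O=2, S=2, P=3, F=Cl=Br=I=1.
#' @return an object of class `mol_formula`: a list with `counts` (named
#'   integer vector of heavy atoms, element symbols in alphabetical order),
#'   `hydrogens`, `valences` (for the elements present), `n` (heavy-atom
#'   total) and `valence_sum`.
#' @examples
#' parse_formula("C7H12O2S")
#' parse_formula("CH4")
#' @export
parse_formula <- function(text, valence_overrides = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: ", sQuote(text))
  syms <- sub("[0-9]*$", "", toks)
  cnts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  cnts[is.na(cnts)] <- 1L

  valences <- default_valences
  if (!is.null(valence_overrides)) {
    stopifnot(!is.null(names(valence_overrides)),
              all(nzchar(names(valence_overrides))))
    ov <- as.integer(valence_overrides)
    if (any(is.na(ov)) || any(ov < 1L)) stop("valences must be positive integers")
    valences[names(valence_overrides)] <- ov
  }

  hydrogens <- sum(cnts[syms == "H"])
  heavy <- syms != "H"
  syms <- syms[heavy]; cnts <- cnts[heavy]
  if (!length(syms)) stop("formula has no heavy atoms")
  unknown <- setdiff(unique(syms), names(valences))
  if (length(unknown))
    stop("unknown element(s) without valence override: ",
         paste(unknown, collapse = ", "))
  counts <- tapply(cnts, syms, sum)
  counts <- counts[order(names(counts))]          # fixed global element order
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (!length(counts) || sum(counts) < 1L)
    stop("formula has no heavy atoms")
  vals <- valences[names(counts)]
  f <- list(counts = counts,
            hydrogens = as.integer(hydrogens),
            valences = stats::setNames(as.integer(vals), names(counts)),
            n = sum(counts),
            valence_sum = sum(counts * as.integer(vals)))
  class(f) <- "mol_formula"
  f
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("Molecular formula: ",
      paste0(names(x$counts), ifelse(x$counts > 1L, x$counts, ""), collapse = ""),
      if (x$hydrogens > 0L) paste0("H", x$hydrogens), "\n", sep = "")
  cat("  heavy atoms n =", x$n,
      " hydrogens h =", x$hydrogens,
      " valence sum V =", x$valence_sum, "\n")
  cat("  valences:", paste(names(x$valences), x$valences, sep = "=",
                           collapse = " "), "\n")
  invisible(x)
}

#' Edge budget of a formula
#'
#' Derives the combinatorial parameters that drive skeleton generation: the
#' bond total counting multiplicity, `(V - h)/2` where `V` is the valence sum
#' and `h` the hydrogen count; the plausible edge-count range of the
#' connected hydrogen-suppressed simple graph; and the maximum vertex degree
#' (the largest valence among the elements present).  The lower edge bound is
#' `max(n - 1, ceiling(bond_total / 3))` because a connected graph needs
#' `n - 1` edges and no bond exceeds multiplicity 3; the upper bound is
#' `min(bond_total, n(n-1)/2)`.
#'
#' A formula with an odd or negative `V - h`, or with fewer bonds than a
#' connected graph requires, has no isomers at all; such budgets are flagged
#' `feasible = FALSE` rather than raising an error, so that the pipeline can
#' report a count of zero.
#'
#' @param f a `mol_formula` from [parse_formula()].
#' @return an object of class `edge_budget`: a list with `bond_total`,
#'   `min_edges`, `max_edges`, `max_degree`, `feasible` and, when infeasible,
#'   `reason`.
#' @examples
#' edge_budget(parse_formula("C7H12O2S"))   # edge range 9..11
#' @export
edge_budget <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  n <- f$n
  slack <- f$valence_sum - f$hydrogens
  b <- list(bond_total = NA_integer_, min_edges = NA_integer_,
            max_edges = NA_integer_,
            max_degree = as.integer(max(f$valences)),
            feasible = TRUE, reason = NULL)
  class(b) <- "edge_budget"
  if (slack < 0L || slack %% 2L != 0L) {
    b$feasible <- FALSE
    b$reason <- "valence sum minus hydrogens is negative or odd: zero isomers"
    return(b)
  }
  bt <- slack %/% 2L
  b$bond_total <- bt
  b$min_edges <- max(n - 1L, as.integer(ceiling(bt / 3)))
  b$max_edges <- min(bt, (n * (n - 1L)) %/% 2L)
  if (bt < n - 1L || b$min_edges > b$max_edges) {
    b$feasible <- FALSE
    b$reason <- "too few bonds for a connected graph: zero isomers"
  }
  b
}

#' @export
print.edge_budget <- function(x, ...) {
  if (!x$feasible) {
    cat("Infeasible edge budget:", x$reason, "\n")
  } else {
    cat("Edge budget: bond total", x$bond_total,
        "; simple-graph edges in [", x$min_edges, ",", x$max_edges,
        "]; max degree", x$max_degree, "\n")
  }
  invisible(x)
}
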