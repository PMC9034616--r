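#' Generate all constitutional isomers of a molecular formula
#'
#' Runs the full three-stage pipeline: connected simple skeletons by
#' canonical augmentation, element assignment (one per automorphism orbit,
#' via the flower factorisation of the group), and bond-multiplicity
#' assignment (one per orbit of the element-preserving subgroup).  The
#' result is exhaustive and duplicate-free: exactly one molecule per
#' isomorphism class of hydrogen-suppressed multigraphs realising the
#' formula.  Distinct Kekule forms of aromatic rings are distinct
#' multigraphs and are all generated; no aromaticity perception is done.
#'
#' @param formula formula string or `mol_formula`.
#' @param valence_overrides passed to [parse_formula()].
#' @param filters a [filter_config()].
#' @param output `"molecules"` to return molecule objects, `"count"` to
#'   count without storing, `"smiles"` to also return one SMILES line per
#'   molecule, `"sdf"` to return SDfile text.
#' @param callback optional function applied to every molecule as it is
#'   produced (forces streaming; nothing is stored).
#' @param use_orbit_shortcut passed to [assign_elements()].
#' @param max_molecules abort if more than this many molecules would be
#'   stored (counting mode is unlimited).
#' @return an object of class `isomer_set`: list with `formula`, `count`,
#'   and (depending on `output`) `molecules`, `smiles` or `sdf`.
#' @examples
#' generate_isomers("C2H6O")$count    # 2: ethanol and dimethyl ether
#' @export
generate_isomers <- function(formula, valence_overrides = NULL,
                             filters = filter_config(),
                             output = c("molecules", "count", "smiles", "sdf"),
                             callback = NULL,
                             use_orbit_shortcut = TRUE,
                             max_molecules = 1e6) {
  output <- match.arg(output)
  f <- if (inherits(formula, "mol_formula")) formula
       else parse_formula(formula, valence_overrides)
  b <- edge_budget(f)
  res <- structure(list(formula = f, count = 0, molecules = list(),
                        smiles = character(), sdf = character()),
                   class = "isomer_set")
  if (!b$feasible) return(finish_isomer_set(res, output))

  want_b5 <- 5L %in% filters$badlists
  store <- is.null(callback) && output != "count"

  take <- function(mol, template) {
    if (want_b5 && !passes_B5(mol)) return(invisible())
    res$count <<- res$count + 1
    if (!is.null(callback)) callback(mol)
    if (store) {
      if (res$count > max_molecules)
        stop("more than max_molecules results; use output=\"count\" or a callback")
      if (output == "molecules")
        res$molecules[[res$count]] <<- mol
      else if (output == "smiles")
        res$smiles[[res$count]] <<- write_smiles(mol, template)
      else
        res$sdf[[res$count]] <<- write_sdf(mol, res$count)
    }
    invisible()
  }

  graphs <- generate_simple_graphs(f, filters = filters)
  for (g in graphs) {
    fp <- find_flowers(g)
    N <- compute_N(g, fp)
    template <- if (store && output != "molecules") build_smiles_template(g)
                else NULL
    assign_elements(g, f, N = N, fp = fp,
                    use_orbit_shortcut = use_orbit_shortcut,
                    callback = function(L) {
      edgeN <- edge_preserving_subgroup(N, L, g)
      efp <- edge_flowers(g, L, fp)
      assign_multiplicities(g, L, f, edgeN = edgeN, efp = efp,
                            callback = function(mol) take(mol, template))
      invisible()
    })
  }
  finish_isomer_set(res, output)
}

finish_isomer_set <- function(res, output) {
  if (output != "molecules") res$molecules <- NULL
  if (output != "smiles") res$smiles <- NULL
  if (output != "sdf") res$sdf <- NULL
  res$output <- output
  res
}

#' @export
print.isomer_set <- function(x, ...) {
  cat("isomer_set: ", format(x$count, big.mark = ","),
      " constitutional isomer(s)\n", sep = "")
  if (!is.null(x$smiles) && length(x$smiles)) {
    show <- utils::head(x$smiles, 10L)
    cat(paste0("  ", show, collapse = "\n"), "\n")
    if (length(x$smiles) > 10L) cat("  ...\n")
  }
  invisible(x)
}
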