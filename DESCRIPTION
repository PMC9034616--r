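Package: isogen
Title: Exhaustive Generation of Constitutional Isomers from a Molecular Formula
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enumerates, exhaustively and without duplicates, all constitutional
    isomers of a molecular formula as hydrogen-suppressed multigraphs with
    implicit hydrogens.  Generation proceeds in three stages: isomorph-free
    generation of connected simple skeleton graphs by canonical augmentation,
    assignment of element symbols to vertices (one assignment per orbit of the
    skeleton's automorphism group, accelerated by factorising the group through
    leaf "flowers"), and assignment of bond multiplicities to edges under
    valence and hydrogen-count constraints.  Includes structural filters
    (ring-count bounds, planarity, forbidden substructures), SMILES and SDfile
    (V2000) writers, a command-line interface, and a brute-force reference
    enumerator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
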