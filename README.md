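# isogen

Exhaustive, duplicate-free generation of the constitutional isomers of a
molecular formula.

Structure generators answer a basic question of computer-assisted structure
elucidation and chemical-space work: *which molecules are consistent with
this formula?*  isogen takes a formula such as `C9H18N2O4`, models each
candidate as a hydrogen-suppressed multigraph (heavy atoms as vertices,
bonds of multiplicity 1–3 as edges, hydrogens implied by unused valence),
and emits exactly one molecule per isomorphism class — no duplicates, no
omissions.  It is written for cheminformatics users who need exhaustive
candidate sets, and for combinatorialists interested in isomorph-free graph
generation.

## Method

Generation runs in three stages, each handling only the symmetry the
previous one left:

1. **Skeletons.** From the valence sum *V*, hydrogen count *h* and heavy-atom
   count *n*, the bond total is *B* = (*V* − *h*)/2 and the connected simple
   skeleton has between max(*n* − 1, ⌈*B*/3⌉) and min(*B*, *n*(*n* − 1)/2)
   edges.  One representative of every isomorphism class in that range (with
   degrees capped by the largest valence) is produced by canonical
   augmentation: a growing graph is accepted only when it is reached along
   its canonical construction path, so isomorph rejection needs no store of
   previous graphs.
2. **Elements.** Symbols are assigned to vertices, one assignment per orbit
   of Aut(*G*), using the factorisation Aut(*G*) = *NM*: *M* is generated by
   swaps of equivalent terminal atoms within "flowers" (maximal leaf sets
   sharing a neighbour, |*M*| = ∏ |*F*ᵢ|!), handled by simple inequalities;
   *N*, the subgroup respecting a positional colouring of the flowers, is
   usually tiny and is scanned explicitly.
3. **Bonds.** Each edge gets a multiplicity in {1,2,3} under the valence and
   hydrogen constraints, one assignment per orbit of the element-preserving
   subgroup (obtained by filtering stage 2's *N*, never recomputed).

Structural filters (5-ring count bounds, planarity, and badlists 5 and 9)
prune at the earliest stage at which they are decidable.  Output is SMILES
or SDfile (V2000), written from per-skeleton templates.  An independent
brute-force enumerator validates the pipeline on small formulas.

## Worked example

```r
library(isogen)

f <- parse_formula("C7H12O2S")
edge_budget(f)
#> Edge budget: bond total 11 ; simple-graph edges in [ 9 , 11 ]; max degree 4

generate_isomers("C2H6O", output = "smiles")$smiles
#> [1] "C(O)C" "O(C)C"               # ethanol and dimethyl ether

r <- generate_isomers("C4H4O", output = "count")
r$count
#> [1] 62                            # furan is one of them

s <- stage1_statistics("C9H18N2O4") # the 15-atom skeleton sweep (~1 min)
s$graphs;  round(s$pct_trivial_N);  s$max_N
#> [1] 534493
#> [1] 58
#> [1] 72
```

The last call counts the 534,493 connected simple skeletons on 15 heavy
atoms with 14–16 edges and degree ≤ 4, and reports that the flower-coloured
automorphism subgroup *N* is trivial for 58% of them and never exceeds
order 72 — the numbers that make the explicit *N*-scan of stage 2 cheap.

From the shell (after installation, see `system.file("..", "exec", package
= "isogen")` or call `isogen::run_cli()` directly):

```sh
isogen C2H6O            # SMILES to stdout, count to stderr
isogen -u C4H4O         # count only
isogen -P -B 5,9 -p0:1 --sdf out.sdf C4H4O
```

## Scope

Constitution only: no stereochemistry, charges, radicals or isotopes.  No
aromaticity perception — distinct Kekulé forms of an aromatic ring are
distinct multigraphs and are all emitted.  One fixed valence per element
per run (overridable, e.g. `-v S=6`).  See the methods vignette
(`vignettes/isomer-generation.Rmd`) for the algorithmic details and design
rationale.
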