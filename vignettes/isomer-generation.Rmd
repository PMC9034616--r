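---
title: "Three-stage generation of constitutional isomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage generation of constitutional isomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isogen)
```

## The problem

Given a molecular formula such as C~9~H~18~N~2~O~4~, enumerate every
*constitutional isomer*: every way of connecting the atoms that respects
their valences, counting two molecules as the same when their molecular
graphs are isomorphic.  isogen represents a molecule as a
hydrogen-suppressed multigraph: vertices are the heavy atoms, edges carry a
bond multiplicity 1–3, and hydrogens are implied by unused valence.  The
requirement is exhaustiveness *and* uniqueness — exactly one representative
per isomorphism class — which is what makes the problem hard: isomer counts
grow into the billions while naive enumeration over labelled graphs
overcounts by up to $n!$.

## The three stages

Generation factors the isomorphism problem into three nested layers, each
of which only has to deal with the symmetry the previous layer left behind.

**Stage 1 — skeletons.**  From the formula we derive an *edge budget*: the
bond total $B = (V - h)/2$ (valence sum minus hydrogens, halved), the edge
range $[\max(n-1, \lceil B/3\rceil),\ \min(B, \binom n2)]$ for the
connected simple graph underlying the molecule, and a degree cap (the
largest valence present).  `generate_simple_graphs()` then emits exactly
one labelled graph per isomorphism class of connected simple graphs in
that range.  It uses canonical augmentation: graphs grow one vertex at a
time (each new vertex attaches to at least one older one, so every
intermediate graph is connected), and a child is kept only when its newest
vertex lies in the automorphism orbit of a canonically chosen deletion
vertex — the non-cut vertex holding the highest canonical position.
Accepted siblings of one parent are deduplicated by canonical form, which
is equivalent to keeping one attachment set per orbit of the parent's
automorphism group.  The correctness of this scheme does not rely on
heuristics; the suite checks it against exhaustive labelled enumeration for
all small budgets.  Two consequences matter operationally: nothing is ever
compared against a store of previously generated graphs (memory stays
constant), and the output is deterministic — there is no seed to vary.

Canonical forms, orbits and automorphism groups come from the package's own
individualization–refinement engine (C++, graphs up to 32 vertices).  The
test suite cross-checks every group order against igraph's BLISS
implementation, which plays no role in generation itself.

**Stage 2 — elements.**  For each skeleton $G$, element symbols are
assigned to vertices with the exact multiset of the formula, subject to
valence ≥ degree at every vertex, keeping one assignment per orbit of
$\mathrm{Aut}(G)$.  An assignment is a list $L$ indexed by vertex number;
the orbit representative is the lexicographically *maximum* list under a
fixed ascending element order (alphabetical: C < N < O < …).  Testing
maximality by scanning the whole group is wasteful, because most of the
symmetry of sparse molecular skeletons is trivial: swaps of equivalent
terminal atoms.  isogen therefore factorises the group through *flowers* —
maximal sets of leaves sharing a neighbour.  The minor subgroup $M$
generated by leaf swaps inside flowers has order $\prod_i |F_i|!$; the
subgroup $N$ of automorphisms preserving a colouring that fixes each
leaf's position inside its flower is a complete set of coset
representatives, and $\mathrm{Aut}(G) = NM$ with unique factorisation.
The maximality test then splits into (a) labels non-increasing inside each
flower — enforced incrementally during the recursion, at no group cost —
and (b) $\gamma(L) \le L$ for the usually tiny $N$.  For the
C~9~H~18~N~2~O~4~ sweep, $N$ is trivial for 58&nbsp;% of the 534,493
skeletons and never exceeds order 72, even though $\mathrm{Aut}(G)$ itself
reaches order 2592.

**Stage 3 — bonds.**  Each edge receives a multiplicity in {1, 2, 3} such
that no atom exceeds its valence and the total equals the bond budget $B$
(equivalently, leftover valence equals the hydrogen count, after which
hydrogens attach in exactly one way).  This is the same orbit problem one
level down: the acting group is the subgroup of stage 2's $N$ that fixes
the element list, converted to its action on the fixed edge order — it is
obtained *only* by filtering, never recomputed — and the flowers become
edge flowers (edges from a centre to its same-element leaves).  The
representative is again the lexicographic maximum, so double and triple
bonds pack toward low-numbered edges within an orbit.

## Parameters and their defaults

* **Valence table** — C=4, N=3, O=2, S=2, P=3, halogens 1; fixed for the
  whole run, overridable per element (`valence_overrides = c(S = 6)`,
  or `-v S=6` on the command line).  A single fixed valence per element is
  a modelling choice: multivalent sulfur within one run is out of scope,
  and published isomer counts for S/P-containing formulas depend on the
  convention chosen, so cross-tool comparisons for such formulas should
  fix the table explicitly.
* **Maximum bond multiplicity 3** — standard organic bonding; it also
  feeds the lower edge bound $\lceil B/3 \rceil$.
* **Filters** — applied at the earliest decidable stage.
  `pentagon_bounds = c(lo, hi)` bounds the number of 5-cycles of the
  skeleton; `planar_only` keeps planar skeletons; badlist 9 rejects a
  skeleton when some atom lies on two distinct cycles of length 3 or 4
  (cycles counted as vertex sets, not smallest-ring systems — an
  interpretation, documented here because ring-perception conventions
  differ); badlist 5 rejects a completed molecule when an atom carries
  exactly two double bonds and otherwise only hydrogens, reading "no other
  neighbour at all" as failing vacuously so that cumulated systems like
  O=C=O are caught.
* **Orbit shortcut** (`use_orbit_shortcut`) — for each member of $N$, the
  least vertex it moves yields one extra inequality usable during the
  element recursion.  It is pure pruning (the tests compare both paths);
  it defaults to on in the pipeline and off in unit tests so that the
  unpruned reference path stays exercised.
* **Group-size cap** (`cap`, default $10^6$) — groups are stored as
  explicit member lists because molecular skeleton groups are small; the
  cap turns a degenerate input into an error instead of an explosion.

## Numerical and representational choices

Counts are accumulated in R doubles, which are exact integers up to
$2^{53}$ — far beyond any total this package can enumerate in practice.
Edge order is frozen when a skeleton is created (sorted vertex pairs);
bond lists index into it, and all lexicographic conventions (element
order ascending alphabetical, representative = maximum, multiplicity
1 < 2 < 3) are fixed package-wide.  Choosing minima instead of maxima
would be equally valid but must be consistent everywhere; the maximum
convention is used because the flower inequality then reads "labels
non-increasing by vertex number", matching the recursion order.

Planarity is decided by a cycle-rank shortcut ($m - n + c \le 3$ implies
planarity, since the Kuratowski graphs have cycle rank 4 and 6 and a
subgraph's rank never exceeds the host's) with exact
Demoucron–Malgrange–Pertuiset face embedding per biconnected component for
the rare richer skeletons.  The implementation is validated against
networkx's planarity checker on random graphs in the test suite.

## Output

SMILES writing uses one template per skeleton — the spanning-tree walk,
parentheses and ring-closure digits are computed once, and each molecule
only fills in atom symbols and bond orders.  Atoms are written bare when
the SMILES standard valence model reproduces the molecule's hydrogen
count, and as bracket atoms with explicit H counts otherwise.  Output
order is raw generation order; canonicalisation is deliberately left to
consumers (the tests canonicalise with OpenBabel to verify round-trips
and pairwise distinctness).  SDfile output is V2000 with zero coordinates
(the generator is constitution-only).

## What the tests do and do not show

The brute-force oracle (`brute_force_count()`) enumerates labelled
graphs, labelings and multiplicity vectors exhaustively and deduplicates
by minimising over all $n!$ permutations; it shares no code path with the
generator.  Pipeline = oracle is verified for a panel of formulas with up
to 6 heavy atoms, with and without every filter, and the group-theoretic
invariants (the $NM$ factorisation with unique decomposition, the
class-maximum characterisation, conservation of bonds and hydrogens) are
checked exhaustively on small instances and across random graphs.  The
test problem sizes — oracle formulas to 6 heavy atoms, factorisation
sweeps to 8 vertices, and the full 534,493-skeleton sweep for
C~9~H~18~N~2~O~4~ — were chosen so the whole suite completes in minutes
on one core while still covering every code path at exhaustive depth.

What passing these tests does *not* show: chemical plausibility.  The
generator emits every valence-consistent multigraph, including strained
rings, cumulated systems (unless badlist 5 is on) and both Kekulé forms
of an aromatic ring — no aromaticity perception is performed, so
graph-theoretically distinct Kekulé structures of the same aromatic
molecule are counted separately.  Synthetic accessibility, stability,
charges, radicals, isotopes and stereochemistry are all out of scope.

## Known limitations

Skeletons are limited to 32 heavy atoms by the engine's bitmask
representation (molecular formulas of interest are far smaller).  Stages
2 and 3 run in R; stage 1 and all group computation run in C++.  The
package comfortably handles the desk-scale end — full enumeration for
formulas whose counts are in the thousands, and skeleton sweeps in the
half-million range — but the billion-molecule totals of large natural
product formulas are a throughput regime it does not attempt:
correctness there is certified by the oracle equivalence and the
conservation invariants rather than by re-running the full count.
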