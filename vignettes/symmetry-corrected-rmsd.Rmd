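---
title: "Symmetry-corrected docking RMSD: model, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-corrected docking RMSD: model, search, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symrmsd)
```

## The metric and why correspondence matters

Docking RMSD compares two poses of the same ligand in a shared receptor
frame: `sqrt(mean(d_i^2))` over pairs of corresponding heavy atoms, with
no superposition of the ligands themselves (superposing would discard
exactly the positional information a docking benchmark is about).
Hydrogens are excluded throughout: they are frequently absent or
inconsistently placed in docking output, and their positions carry
little information about the pose.

The only free choice in the formula is the atom correspondence, and it
matters enormously for symmetric molecules. A correspondence is
*chemically valid* if it preserves elements and the bond network — i.e.
if it is an isomorphism between the two molecular graphs. The metric
this package computes is the minimum RMSD over all such isomorphisms.
Two baselines bracket it:

* **naive** — the file-order identity. An upper bound whenever file
  order is itself chemically valid; inflated by any symmetry the pose
  pair exploits.
* **Hungarian** — the element-constrained minimum-cost assignment,
  bonds ignored. A relaxation over a superset of the valid
  correspondences, hence a lower bound; it can (and on near-symmetric
  molecules does) return values no rigid molecule could realize.

The ordering `hungarian <= corrected <= naive` (the last whenever
identity is valid) is a structural fact, and the test suite checks it on
every fixture pair.

## Input model

Poses arrive as TRIPOS MOL2 files. The reader keeps only heavy atoms
(H and D stripped, with their bonds), takes the element as the SYBYL
atom-type substring before the first `.`, and stores bonds as a
symmetric table of lowercase type strings (`"1"`, `"2"`, `"ar"`,
`"am"`, ...). Only the first molecule of a multi-molecule file is read
(one pose per file is the tool's contract) and sections after BOND are
ignored, since docking pipelines append substructure records of no
relevance here.

Before any search, the two graphs are checked to be the same molecule:
equal atom counts, element multisets, and bond counts. Bond *types* are
compared as whole-molecule per-type multisets. If they disagree — the
classic case is one program writing aromatic rings as `"ar"` and another
as alternating `"1"`/`"2"` Kekulé bonds — both graphs are stripped to
generic bonds and matching proceeds on connectivity alone. The
comparability decision is global rather than per-bond: local repair
would have to guess which file's typing is "right", whereas stripping is
symmetric and cannot create false mismatches. `"am"` (amide) and `"1"`
are kept distinct when both files use them consistently; the stripping
fallback covers files that disagree.

## Atom identity search

For each query atom the candidate partners are template atoms with the
same element, then the same depth-1 signature (sorted multiset of
(bond type, neighbour element) pairs), then the same depth-2 signature
(sorted multiset of (bond type, neighbour depth-1 signature) pairs).
Sorting string-encoded pairs gives deterministic multiset equality with
no canonical atom-ranking machinery.

Refinement deliberately stops at depth 2. Deeper refinement would only
shrink the candidate sets, never change the final mapping — the
downstream search enforces full bond consistency anyway — and two rounds
already separate everything the search cannot cheaply handle. The
candidate sets may therefore *over*-approximate chemical equivalence
(e.g. a 6-ring and two disjoint triangles of the same composition are
indistinguishable at depth 2); the search detects such cases and reports
that no isomorphism exists. The depth-2 encoding includes the connecting
bond's type together with the neighbour's full depth-1 signature, so
second-shell bond types participate in the comparison.

The product of the candidate-set sizes is the state-space size, reported
exactly: a C60 self-pair yields 60^60, a 107-digit integer, kept as a
base-1e7 limb vector (the only operation needed is multiplication by a
small integer, and every intermediate stays far below 2^53, so plain
doubles are exact).

## The search

Query atoms are placed in a fixed order: fewest candidates first, then
most bonds into the already-placed prefix (recomputed greedily as the
order is built), then file order. At each node the surviving candidates
are tried in ascending squared-distance order. A candidate is feasible
if it is unclaimed and bond-consistent with every placed atom — the
check is a single type-code equality per placed atom, which enforces
both directions at once (query bonds must exist identically in the
template *and* template bonds must not appear where the query has none).

Dead-end elimination prunes a branch when

```
cumulative squared sum
  + sum over unassigned atoms of min d^2 to a still-unclaimed candidate
  >= best complete sum so far
```

The bound is admissible (it ignores one-to-one conflicts among the
unassigned atoms, so it never overestimates), hence pruning is lossless:
the returned cost equals a brute-force enumeration's on every instance
the oracle can handle, a property the suite verifies on hundreds of
seeded random molecules, and disabling the bound changes node counts but
never the cost. Excluding claimed candidates from the per-atom minima is
done with a two-smallest-values trick so the bound specialized to the
candidate under consideration costs O(1).

Ties between equal-cost complete mappings resolve to the first one
reached under the deterministic order, making output reproducible
byte-for-byte. The core is ~100 lines of C++ (recursion depth equals the
atom count; frames are a few words, so molecules of a few hundred atoms
are far from any stack limit). On a C60 self-pair the first descent
finds the zero-cost identity mapping and the bound then closes the
entire remaining 60^60 space: the whole search visits a few hundred
nodes and runs in milliseconds.

## Baselines

The Hungarian baseline solves the element-blocked linear-sum assignment
on squared distances. Because the element constraint makes the cost
matrix block-diagonal, each element's square sub-problem is solved
independently; this also removes any need for cross-element sentinel
costs. Each block is solved exactly via maximum-weight bipartite
matching (igraph) on weights `K - d^2` with `K = n * max(d^2) + 1`,
which forces the matching to be perfect and makes maximum weight
equivalent to minimum cost. Any exact assignment solver would do — the
baseline is defined by its optimum, not its algorithm — and tests verify
the optimum against exhaustive permutation enumeration on small blocks.

## Fixtures: what they emulate, and what they do not

All test inputs are generated, deterministically, from explicit seeds:

* `make_benzene()` — complete 6-fold ring symmetry; circumradius 1.39 Å
  (the aromatic C–C bond length, and also the hexagon side).
* `make_c60()` — the worst observed natural case of whole-molecule
  symmetry. Truncated-icosahedron vertices; all bonds scaled to 1.40 Å
  (in the idealized Archimedean geometry the two bond classes have equal
  length, so the real molecule's 1.40/1.46 split collapses to one
  value). Pentagon edges are typed `"1"` and hexagon–hexagon edges
  `"2"`, identified combinatorially from the 12 icosahedral five-fold
  axes. The alternating typing — rather than all-aromatic — exercises
  typed-bond matching while every carbon still sees the same {1,1,2}
  neighbourhood, preserving the full 60-fold equivalence.
* `make_chain()` — the fully asymmetric control: singleton candidate
  sets, no correction possible.
* `make_para_ring()` — a ring whose unsubstituted carbons share depth-1
  signatures but split at depth 2; the reason one refinement round is
  not enough.
* `make_pseudo_mirror()` — a mirror-symmetric carbon zig-zag broken by a
  single oxygen substituent. Paired with its own reflection it
  reproduces the canonical assignment-baseline failure: the carbons
  match their mirror images at near-zero cost, the lone oxygen cannot,
  and the Hungarian value (2.61 Å) falls strictly below the true
  bond-preserving optimum (4.15 Å).
* `make_random_tree(n, seed)` — random labelled trees, elements from
  {C, N, O, S}, bond types from {1, 2}, n ≤ 12 so the brute-force
  oracle's enumeration stays trivially feasible. Pose pairs add a rigid
  motion, a file-order shuffle, and Gaussian coordinate noise
  (σ = 0.15 Å by default — the scale of coordinate differences between
  well-converged docked replicas of one conformer).

What the generator does *not* emulate: conformational flexibility (all
pose pairs are rigid-motion-plus-noise variants of one conformer),
force-field-realistic geometry, protonation states, or real docking
decoys. Passing tests therefore demonstrate the correctness of the
correspondence search and the metric, not robustness to conformer
mismatch — which is a property of the inputs, not of the metric.

## Numerical choices and degenerate inputs

* Squared distances are computed from explicit coordinate differences,
  so coincident atoms contribute exactly zero (the expanded
  `q^2 + t^2 - 2qt` form leaves ~1e-16 cancellation residue per atom,
  which surfaces as a spurious ~1e-8 RMSD on identical poses).
* DEE pruning uses `>=` against the incumbent, so equal-cost ties never
  displace the first-found optimum.
* MOL2 output writes coordinates to 4 decimal places; round-tripping is
  exact to 5e-5 Å. RMSD values print to 3 decimals; internal arithmetic
  is double precision.
* Disconnected graphs (salts, fragments) are legal; the search order's
  bond-count criterion simply never links across components, and
  correctness is unaffected.
* A pair whose signatures match but whose graphs are not isomorphic
  (possible, since refinement stops at depth 2) exhausts the search and
  raises a no-isomorphism error rather than returning a wrong value.

## Problem sizes used in the checks

The randomized oracle-agreement check runs 200 molecules of 4–12 heavy
atoms — sizes at which exhaustive enumeration of all element-preserving
bijections is itself instantaneous, so the oracle is unquestionably
independent ground truth. The C60 searches run on the full 60-atom
molecule. These sizes keep the complete suite under a few seconds while
covering the regimes that matter: heavy symmetry (benzene, C60), near
symmetry (pseudo-mirror), and bulk randomized structure.

## Known limitations

* Both inputs must be the same molecule; there is no partial or
  maximum-common-substructure matching.
* Exhaustive search is worst-case exponential. DEE makes every case
  tried here fast, but a highly symmetric molecule whose poses are far
  apart geometrically weakens the bound; no polynomial guarantee exists
  (graph isomorphism is not known to be polynomial).
* Bond-type semantics are purely string-based; no aromaticity
  perception or valence model reconciles chemically equivalent typings
  beyond the global stripping fallback.
* Stereochemistry is invisible to the graph: a mapping may correspond
  to the mirror enantiomer if coordinates permit it.
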