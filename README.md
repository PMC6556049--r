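# symrmsd

Symmetry-corrected docking RMSD between two poses of the same ligand, via
molecular-graph isomorphism.

## The problem

Protein–ligand docking programs are benchmarked by how closely their
predicted ligand poses reproduce a reference pose, measured as the
root-mean-square deviation between corresponding heavy atoms in a common
receptor frame (no ligand superposition):

```
RMSD = sqrt( (1/N) * sum_i d_i^2 )
```

where `N` is the number of heavy atoms and `d_i` the Euclidean distance
between the *i*-th pair of *corresponding* atoms. The catch is the word
"corresponding". The naive choice — atom *i* of one file corresponds to
atom *i* of the other — is wrong for symmetric molecules: rotate one of
two perfectly overlapped benzene rings by 60° and the overlap is
chemically unchanged, yet every file-order atom pair is now one ring
chord apart, so the naive RMSD jumps from 0 to the ring circumradius.
Conversely, the popular Hungarian-assignment fix (match atoms of the same
element at minimum total squared distance, ignoring bonds) can pair atoms
in ways no rigid molecule could realize, *under*-estimating the RMSD.

`symrmsd` computes the true minimum: the RMSD over all atom
correspondences that preserve both elements and the bond network
(graph isomorphisms between the two poses). It does so exactly, by

1. an **atom identity search** — each query atom's candidate partners are
   the template atoms with the same element and the same depth-1 and
   depth-2 neighbour signatures (bond types included); the product of the
   candidate-set sizes is the size of the mapping state space, reported
   exactly in arbitrary precision;
2. an **exhaustive depth-first search** over those candidates with
   one-to-one and bond-consistency feasibility checks and **dead-end
   elimination**: a branch is abandoned as soon as its accumulated squared
   distance plus an admissible lower bound cannot beat the best complete
   mapping found so far. The pruning never discards the optimum, so the
   returned mapping is provably minimal.

The naive and element-constrained Hungarian baselines are included for
comparison, as is a deterministic fixture generator (benzene,
buckminsterfullerene, chains, pseudo-mirror molecules, seeded random
trees) used by the test suite.

## Worked example

```r
library(symrmsd)

b1 <- make_benzene(circumradius = 1.39)
b2 <- transform_pose(b1, axis = c(0, 0, 1), angle = pi / 3)  # 60° ring turn

dock_rmsd(b1, b2)
#> RMSD: 0.000
#> Method: symmetry
#> Total possible mappings: 46656

naive_rmsd(b1, b2)
#> [1] 1.39
```

The corrected RMSD is zero — the rotated ring is chemically the same
overlap, and one of the 6^6 = 46656 candidate mappings (a cyclic shift)
realizes it — while the naive file-order RMSD equals the circumradius,
1.39 Å, because every atom appears displaced by one chord.

Buckminsterfullerene is the stress test: all 60 carbons are chemically
equivalent, so a C60 self-pair has 60^60 possible mappings (a 107-digit
number). Dead-end elimination collapses this to a few hundred search
nodes:

```r
c60 <- make_c60()
r <- dock_rmsd(c60, c60)
r$rmsd                              #> 0
as.character(r$total_mappings)      #> "488736779806892574893227522737…" (107 digits)
r$nodes                             #> 125
```

The Hungarian baseline's flaw shows on a near-mirror-symmetric molecule
paired with its own reflection:

```r
pm <- make_pseudo_mirror()
mirrored <- pm; mirrored$coords[, 1] <- -mirrored$coords[, 1]
hungarian_rmsd(pm, mirrored)        #> 2.613  (chemically impossible mapping)
dock_rmsd(pm, mirrored)$rmsd        #> 4.153  (true bond-preserving optimum)
```

## Command line

```sh
symrmsd query.mol2 template.mol2 [--naive|--hungarian] [--no-bond-types] [--json] [--no-mapping] [-v]
```

Reads two TRIPOS MOL2 files (heavy atoms only; hydrogens are stripped),
prints the RMSD, the optimal mapping and the exact mapping count. Exit
codes: 0 success, 1 domain error (not the same molecule, no isomorphism,
parse failure), 2 usage error. The wrapper lives in `exec/symrmsd` after
installation.

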