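Package: symrmsd
Title: Symmetry-Corrected Docking RMSD via Molecular Graph Isomorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the minimum symmetry-corrected root-mean-square deviation
    (RMSD) between two poses of the same ligand in a common receptor frame,
    without ligand superposition. Chemically equivalent atoms are identified by
    element and neighbour-signature refinement, and the optimal bond-preserving
    atom mapping is found by an exhaustive depth-first search with dead-end
    elimination pruning. Includes naive (file-order) and element-constrained
    Hungarian-assignment baselines, a TRIPOS MOL2 reader and writer restricted
    to heavy atoms, deterministic synthetic-molecule fixtures (benzene,
    buckminsterfullerene, chains, pseudo-mirror molecules, random trees), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
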