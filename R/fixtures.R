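# Deterministic synthetic molecules and pose transformations. These
# generators provide every test input for the package: fully symmetric
# rings (benzene), the most symmetric molecule observed in nature
# (buckminsterfullerene), asymmetric chains, a para-substituted ring
# whose carbons need depth-2 signatures to separate, a pseudo-mirror
# molecule reproducing the failure mode of assignment-based symmetry
# correction, and seeded random trees for randomized oracle testing.
# All randomness flows through explicit integer seeds; the same
# arguments always produce bit-identical graphs.

#' Benzene carbon skeleton
#'
#' Six carbons on a regular hexagon in the z = 0 plane joined by six
#' aromatic ("ar") ring bonds. The hexagon side equals the circumradius,
#' so the default reproduces the aromatic C-C bond length of 1.39
#' Angstroms.
#'
#' @param circumradius distance from ring center to each carbon
#'   (Angstroms).
#' @return A `molgraph` of 6 carbons.
#' @export
make_benzene <- function(circumradius = 1.39) {
  stopifnot(circumradius > 0)
  theta <- 2 * pi * (0:5) / 6
  coords <- cbind(circumradius * cos(theta), circumradius * sin(theta), 0)
  bonds <- matrix("", 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    bonds[i, j] <- bonds[j, i] <- "ar"
  }
  molecular_graph(rep("C", 6), coords, bonds, name = "benzene")
}

#' Buckminsterfullerene (C60)
#'
#' Sixty carbons at the vertices of a truncated icosahedron (the cyclic
#' permutations of (0, +/-1, +/-3 phi), (+/-1, +/-(2+phi), +/-2 phi),
#' (+/-phi, +/-2, +/-(2 phi + 1)) with phi the golden ratio), uniformly
#' scaled so bonds are 1.40 Angstroms. The 90 edges split into 60
#' pentagon edges (typed "1") and 30 hexagon-hexagon edges (typed "2"),
#' identified combinatorially via the 12 icosahedral five-fold axes;
#' every vertex has degree 3 with typed neighbourhood {1, 1, 2}, so all
#' 60 carbons are chemically equivalent and a self-pair has a state
#' space of 60^60 possible mappings.
#'
#' @return A `molgraph` of 60 carbons and 90 bonds.
#' @export
make_c60 <- function() {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    as.matrix(expand.grid(0, c(-1, 1), c(-3 * phi, 3 * phi))),
    as.matrix(expand.grid(c(-1, 1), c(-(2 + phi), 2 + phi),
                          c(-2 * phi, 2 * phi))),
    as.matrix(expand.grid(c(-phi, phi), c(-2, 2),
                          c(-(2 * phi + 1), 2 * phi + 1))))
  coords <- rbind(base, base[, c(2, 3, 1)], base[, c(3, 1, 2)])
  dimnames(coords) <- NULL
  # all edges have length 2 in these coordinates
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  edges <- which(D < 2 + 1e-6 & upper.tri(D), arr.ind = TRUE)
  # pentagon membership: for each icosahedral vertex axis, the 5 vertices
  # of maximal projection form one pentagon
  ax <- as.matrix(expand.grid(0, c(-1, 1), c(-phi, phi)))
  axes <- rbind(ax, ax[, c(2, 3, 1)], ax[, c(3, 1, 2)])
  pent_key <- character(0)
  for (k in seq_len(nrow(axes))) {
    pent <- order(coords %*% axes[k, ], decreasing = TRUE)[1:5]
    for (i in 1:4) for (j in (i + 1):5) {
      u <- pent[i]; v <- pent[j]
      if (D[u, v] < 2 + 1e-6)
        pent_key <- c(pent_key, paste(min(u, v), max(u, v)))
    }
  }
  bonds <- matrix("", 60, 60)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    type <- if (paste(min(i, j), max(i, j)) %in% pent_key) "1" else "2"
    bonds[i, j] <- bonds[j, i] <- type
  }
  molecular_graph(rep("C", 60), coords * (1.40 / 2), bonds, name = "C60")
}

#' Linear chain molecule
#'
#' Atoms placed along the x axis at a fixed spacing, bonded in sequence.
#' With distinct elements (the default C-N-O) every atom is chemically
#' unique, giving the fully asymmetric control case: all candidate sets
#' are singletons and no symmetry correction is possible or needed.
#'
#' @param elements element symbols along the chain.
#' @param bond_types bond types between consecutive atoms (length one
#'   less than `elements`).
#' @param bond_length spacing in Angstroms.
#' @return A `molgraph`.
#' @export
make_chain <- function(elements = c("C", "N", "O"),
                       bond_types = c("1", "2"),
                       bond_length = 1.5) {
  n <- length(elements)
  stopifnot(n >= 2, length(bond_types) == n - 1, bond_length > 0)
  coords <- cbind((seq_len(n) - 1) * bond_length, 0, 0)
  bonds <- matrix("", n, n)
  for (i in seq_len(n - 1)) {
    bonds[i, i + 1] <- bonds[i + 1, i] <- as.character(bond_types[i])
  }
  molecular_graph(elements, coords, bonds, name = "chain")
}

#' Para-disubstituted six-ring
#'
#' A benzene ring carrying one nitrogen at position 1 and one oxygen at
#' position 4 (radially outward, single bonds). The four unsubstituted
#' ring carbons all share the same depth-1 neighbour signature
#' ({(ar,C) x2}), but the pair next to the nitrogen and the pair next to
#' the oxygen are chemically distinct -- only their depth-2 signatures
#' differ. This is the canonical case showing why one round of
#' neighbour comparison is not enough.
#'
#' @param circumradius ring circumradius (Angstroms).
#' @param sub_length ring-substituent bond length (Angstroms).
#' @return A `molgraph` of 8 heavy atoms.
#' @export
make_para_ring <- function(circumradius = 1.39, sub_length = 1.4) {
  stopifnot(circumradius > 0, sub_length > 0)
  theta <- 2 * pi * (0:5) / 6
  ring <- cbind(circumradius * cos(theta), circumradius * sin(theta), 0)
  out1 <- ring[1, ] * (circumradius + sub_length) / circumradius
  out4 <- ring[4, ] * (circumradius + sub_length) / circumradius
  coords <- rbind(ring, out1, out4)
  bonds <- matrix("", 8, 8)
  for (i in 1:6) {
    j <- i %% 6 + 1
    bonds[i, j] <- bonds[j, i] <- "ar"
  }
  bonds[1, 7] <- bonds[7, 1] <- "1"
  bonds[4, 8] <- bonds[8, 4] <- "1"
  molecular_graph(c(rep("C", 6), "N", "O"), coords, bonds,
                  name = "para_ring")
}

#' Pseudo-mirror molecule
#'
#' A five-carbon zig-zag chain arranged mirror-symmetrically about the
#' yz plane, with the mirror symmetry broken by a single hydroxyl-like
#' oxygen on one end. Geometrically the molecule is nearly its own
#' mirror image, but chemically it is fully asymmetric (every candidate
#' set is a singleton). Pairing it with its own reflection reproduces
#' the failure mode of the bond-blind assignment baseline: the
#' assignment maps the carbons across the mirror at near-zero cost,
#' yielding an RMSD strictly below the true bond-preserving value.
#'
#' @return A `molgraph` of 6 heavy atoms.
#' @export
make_pseudo_mirror <- function() {
  coords <- rbind(
    c(-2.5, 0.0, 0),   # C1 (carries the oxygen)
    c(-1.25, 0.6, 0),  # C2
    c(0.0, 0.0, 0),    # C3, on the mirror plane
    c(1.25, 0.6, 0),   # C4
    c(2.5, 0.0, 0),    # C5
    c(-3.2, 1.1, 0))   # O6
  bonds <- matrix("", 6, 6)
  for (i in 1:4) bonds[i, i + 1] <- bonds[i + 1, i] <- "1"
  bonds[1, 6] <- bonds[6, 1] <- "1"
  molecular_graph(c(rep("C", 5), "O"), coords, bonds,
                  name = "pseudo_mirror")
}

#' Seeded random tree molecule
#'
#' A random labelled tree of up to 12 heavy atoms: atom i (i > 1)
#' attaches to a uniformly chosen earlier atom with a random bond type
#' from {1, 2}; elements are drawn from {C, N, O, S}; coordinates grow
#' from the parent atom in a random direction at 1.5 Angstroms. Sizes
#' are capped so the brute-force oracle's enumeration stays feasible.
#' The same `(n, seed)` pair always produces an identical graph.
#'
#' @param n number of heavy atoms (2 to 12).
#' @param seed integer seed.
#' @return A `molgraph`.
#' @export
make_random_tree <- function(n, seed) {
  stopifnot(n >= 2, n <= 12)
  with_seed(seed, {
    elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
    coords <- matrix(0, n, 3)
    bonds <- matrix("", n, n)
    for (i in 2:n) {
      parent <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      coords[i, ] <- coords[parent, ] + 1.5 * dir
      type <- sample(c("1", "2"), 1L)
      bonds[i, parent] <- bonds[parent, i] <- type
    }
    molecular_graph(elements, coords, bonds,
                    name = sprintf("tree%d_seed%d", n, seed))
  })
}

#' Rigid-body pose transformation
#'
#' Rotates a pose about an axis through the origin (Rodrigues formula)
#' and then translates it. Rigid motions preserve every pairwise
#' interatomic distance, so they generate alternative poses of the same
#' conformer.
#'
#' @param graph a `molgraph`.
#' @param axis rotation axis (length-3, need not be unit).
#' @param angle rotation angle in radians.
#' @param translation length-3 translation vector (Angstroms).
#' @return The transformed `molgraph`.
#' @export
transform_pose <- function(graph, axis = c(0, 0, 1), angle = 0,
                           translation = c(0, 0, 0)) {
  stopifnot(inherits(graph, "molgraph"), length(axis) == 3,
            length(translation) == 3, sum(axis^2) > 0)
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  graph$coords <- graph$coords %*% t(R) +
    matrix(translation, graph$n_atoms, 3, byrow = TRUE)
  graph
}

#' Relabel (reorder) the atoms of a pose
#'
#' Returns the same molecule with atom `i` of the result taken from atom
#' `permutation[i]` of the input; coordinates, elements, names and the
#' bond table are permuted consistently. Relabelling emulates what
#' docking pipelines do to atom order and never changes the
#' symmetry-corrected RMSD to any third pose.
#'
#' @param graph a `molgraph`.
#' @param permutation an integer permutation of `1:n_atoms`.
#' @return The relabelled `molgraph`.
#' @export
relabel <- function(graph, permutation) {
  stopifnot(inherits(graph, "molgraph"))
  n <- graph$n_atoms
  permutation <- as.integer(permutation)
  if (length(permutation) != n || !setequal(permutation, seq_len(n)))
    stop_symrmsd("bad_permutation",
                 "permutation must be a bijection over 1:n_atoms")
  molecular_graph(graph$elements[permutation],
                  graph$coords[permutation, , drop = FALSE],
                  graph$bonds[permutation, permutation],
                  name = graph$name,
                  atom_names = graph$atom_names[permutation])
}

#' Add seeded Gaussian coordinate noise
#'
#' Perturbs every coordinate with independent N(0, sigma^2) noise under
#' an explicit seed, emulating the small geometric differences between
#' docked poses of one conformer.
#'
#' @param graph a `molgraph`.
#' @param sigma noise standard deviation (Angstroms, >= 0).
#' @param seed integer seed.
#' @return The perturbed `molgraph`.
#' @export
perturb <- function(graph, sigma, seed) {
  stopifnot(inherits(graph, "molgraph"), sigma >= 0)
  with_seed(seed, {
    graph$coords <- graph$coords +
      matrix(stats::rnorm(3 * graph$n_atoms, sd = sigma), ncol = 3)
    graph
  })
}

#' Registry of canonical named fixtures
#'
#' The molecules used throughout the documentation and tests, as a
#' named list of zero-argument generators.
#'
#' @return A named list of functions, each returning a `molgraph`.
#' @export
fixture_registry <- function() {
  list(
    benzene = function() make_benzene(),
    c60 = function() make_c60(),
    chain = function() make_chain(),
    para_ring = function() make_para_ring(),
    pseudo_mirror = function() make_pseudo_mirror(),
    tree8 = function() make_random_tree(8, seed = 7),
    tree12 = function() make_random_tree(12, seed = 11)
  )
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
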