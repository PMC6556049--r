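#' RMSD of a given atom correspondence
#'
#' The root-mean-square deviation between two poses in a common receptor
#' frame: `sqrt(mean(d_i^2))` where `d_i` is the Euclidean distance
#' between the i-th pair of corresponding heavy atoms. No superposition
#' is performed -- this is docking RMSD, not a conformational distance.
#'
#' @param query,template `molgraph` objects with equal atom counts.
#' @param mapping integer vector over all atoms; `mapping[i]` is the
#'   template atom corresponding to query atom `i`. Must be a bijection.
#' @return RMSD in Angstroms.
#' @export
#' @examples
#' b <- make_benzene()
#' rmsd_of_mapping(b, b, seq_len(6))  # 0
rmsd_of_mapping <- function(query, template, mapping) {
  stopifnot(inherits(query, "molgraph"), inherits(template, "molgraph"))
  n <- query$n_atoms
  if (length(mapping) != n || anyNA(mapping) ||
      !setequal(mapping, seq_len(template$n_atoms)))
    stop_symrmsd("bad_mapping",
                 "mapping must be a bijection over all heavy atoms")
  d2 <- rowSums((query$coords - template$coords[mapping, , drop = FALSE])^2)
  sqrt(mean(d2))
}

#' Naive (file-order) RMSD baseline
#'
#' Assumes the i-th atom of one file corresponds to the i-th atom of the
#' other, the historical default. Valid for asymmetric molecules whose
#' files agree in atom order, but artificially inflated for symmetric
#' molecules: two benzene poses related by a 60-degree ring rotation
#' overlap perfectly, yet every atom appears displaced by one ring chord.
#' Only atom counts are checked.
#'
#' @param query,template `molgraph` objects with equal atom counts.
#' @return RMSD in Angstroms.
#' @export
naive_rmsd <- function(query, template) {
  stopifnot(inherits(query, "molgraph"), inherits(template, "molgraph"))
  if (query$n_atoms != template$n_atoms)
    stop_symrmsd("not_same_molecule", sprintf(
      "heavy-atom counts differ (%d vs %d)", query$n_atoms, template$n_atoms))
  rmsd_of_mapping(query, template, seq_len(query$n_atoms))
}

#' Element-constrained Hungarian-assignment RMSD baseline
#'
#' Solves the linear-sum assignment problem minimizing total squared
#' interpose distance, with assignments allowed only between atoms of
#' the same element, then applies the RMSD formula. Bonds are
#' deliberately ignored: this reproduces the known flaw of
#' assignment-based symmetry correction, which can return chemically
#' impossible correspondences and therefore RMSD values below the true
#' bond-preserving optimum.
#'
#' @param query,template `molgraph` objects with equal element
#'   multisets.
#' @param details if `TRUE`, return a list with `rmsd`, `mapping` and
#'   `total_sq` instead of the bare RMSD.
#' @return RMSD in Angstroms (or a list when `details = TRUE`).
#' @export
hungarian_rmsd <- function(query, template, details = FALSE) {
  stopifnot(inherits(query, "molgraph"), inherits(template, "molgraph"))
  n <- query$n_atoms
  if (n != template$n_atoms ||
      !identical(sort(tolower(query$elements)),
                 sort(tolower(template$elements))))
    stop_symrmsd("not_same_molecule", "element multisets differ")
  d2 <- squared_distance_matrix(query, template)
  mapping <- integer(n)
  # The element constraint makes the cost matrix block-diagonal, so each
  # element's square sub-assignment is solved independently.
  for (el in unique(tolower(query$elements))) {
    qi <- which(tolower(query$elements) == el)
    ti <- which(tolower(template$elements) == el)
    if (length(qi) == 1L) {
      mapping[qi] <- ti
      next
    }
    mapping[qi] <- ti[solve_assignment(d2[qi, ti, drop = FALSE])]
  }
  r <- rmsd_of_mapping(query, template, mapping)
  if (details) list(rmsd = r, mapping = mapping,
                    total_sq = sum(d2[cbind(seq_len(n), mapping)]))
  else r
}

# Exact minimum-cost square assignment via maximum-weight bipartite
# matching. Costs are flipped as w = K - cost with K large enough that
# any perfect matching outweighs any deficient one, so the max-weight
# matching is forced perfect and realizes the min-cost assignment.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  dimnames(cost) <- NULL  # named matrices make igraph report names, not indices
  K <- n * max(cost) + 1
  g <- igraph::graph_from_biadjacency_matrix(K - cost, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight,
                                   eps = 1e-9)
  perm <- as.integer(m$matching[seq_len(n)]) - n
  if (anyNA(perm) || !setequal(perm, seq_len(n)))
    stop_symrmsd("internal", "assignment solver failed to return a permutation")
  perm
}

#' Symmetry-corrected docking RMSD between two ligand poses
#'
#' The main entry point. Validates that the two poses are the same
#' molecule, falls back to bond-type stripping when the files disagree
#' on bond-type conventions, runs the atom identity search, and finds
#' the bond-preserving atom mapping of globally minimal RMSD by
#' exhaustive search with dead-end elimination. The naive and Hungarian
#' baselines are available through `method`.
#'
#' @param query,template `molgraph` objects (see [read_mol2()]), or
#'   paths to MOL2 files.
#' @param method `"symmetry"` (default, the corrected RMSD), `"naive"`
#'   (file-order correspondence), or `"hungarian"` (element-constrained
#'   assignment ignoring bonds).
#' @param strip_types force bond-type stripping even when the two files'
#'   bond-type multisets agree.
#' @return An object of class `rmsd_result`: a list with `rmsd`
#'   (Angstroms), `mapping`, `total_mappings` (exact `mapping_count`;
#'   `NULL` for the baselines), `bond_types_stripped`, `symmetric`
#'   (`TRUE` iff more than one possible mapping), `method`, `n_atoms`,
#'   and `nodes` (search effort).
#' @export
#' @examples
#' b1 <- make_benzene()
#' b2 <- transform_pose(b1, axis = c(0, 0, 1), angle = pi / 3)
#' dock_rmsd(b1, b2)$rmsd        # 0: the rotation is a ring symmetry
#' naive_rmsd(b1, b2)            # the circumradius, 1.39
dock_rmsd <- function(query, template,
                      method = c("symmetry", "naive", "hungarian"),
                      strip_types = FALSE) {
  method <- match.arg(method)
  if (is.character(query)) query <- read_mol2(query)
  if (is.character(template)) template <- read_mol2(template)
  stopifnot(inherits(query, "molgraph"), inherits(template, "molgraph"))
  n <- query$n_atoms

  if (method == "naive") {
    r <- naive_rmsd(query, template)
    return(new_rmsd_result(r, seq_len(n), NULL, FALSE, NA, method, n, 0))
  }

  v <- validate_pair(query, template)
  stripped <- strip_types || !v$bond_types_comparable
  if (stripped) {
    query <- strip_bond_types(query)
    template <- strip_bond_types(template)
  }

  if (method == "hungarian") {
    h <- hungarian_rmsd(query, template, details = TRUE)
    return(new_rmsd_result(h$rmsd, h$mapping, NULL, stripped, NA, method, n, 0))
  }

  candidates <- compute_candidates(query, template)
  total <- count_total_mappings(candidates)
  fit <- find_optimal_mapping(query, template, candidates)
  new_rmsd_result(sqrt(fit$total_sq / n), fit$mapping, total, stripped,
                  as.character(total) != "1", method, n, fit$nodes)
}

new_rmsd_result <- function(rmsd, mapping, total, stripped, symmetric,
                            method, n, nodes) {
  structure(list(rmsd = rmsd, mapping = mapping, total_mappings = total,
                 bond_types_stripped = stripped, symmetric = symmetric,
                 method = method, n_atoms = n, nodes = nodes),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("RMSD: %.3f\n", x$rmsd))
  cat("Method:", x$method, "\n")
  if (!is.null(x$total_mappings))
    cat("Total possible mappings:", as.character(x$total_mappings), "\n")
  if (isTRUE(x$bond_types_stripped))
    cat("Bond types stripped (files disagreed or stripping forced)\n")
  invisible(x)
}
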