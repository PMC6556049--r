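#' Canonical neighbour signature of an atom
#'
#' The depth-1 signature of an atom is the sorted multiset of
#' (bond type, neighbour element) pairs over its bonded neighbours; the
#' depth-2 signature is the sorted multiset of (bond type, neighbour
#' depth-1 signature) pairs. Signatures are encoded as strings by
#' lexicographic sorting, so they are order-independent and
#' deterministic: two atoms have equal signatures iff their (typed)
#' neighbourhoods are indistinguishable to that depth.
#'
#' @param graph a `molgraph`.
#' @param atom 1-based atom index.
#' @param depth 1 or 2.
#' @return A single string; equal strings mean equal neighbourhood
#'   multisets.
#' @export
#' @examples
#' b <- make_benzene()
#' neighbor_signature(b, 1, depth = 1)  # {(ar,C) x2}, shared by all six
neighbor_signature <- function(graph, atom, depth = 1) {
  stopifnot(inherits(graph, "molgraph"),
            atom >= 1, atom <= graph$n_atoms, depth %in% c(1, 2))
  sig1 <- function(i) {
    nb <- which(graph$bonds[i, ] != "")
    paste(sort(paste0(graph$bonds[i, nb], ":", graph$elements[nb])),
          collapse = "|")
  }
  if (depth == 1) return(sig1(atom))
  nb <- which(graph$bonds[atom, ] != "")
  parts <- vapply(nb, function(j)
    paste0(graph$bonds[atom, j], ":(", sig1(j), ")"), "")
  paste(sort(parts), collapse = "|")
}

#' Atom identity search: candidate template atoms per query atom
#'
#' For each query atom, the template atoms considered chemically
#' equivalent: same element, same depth-1 neighbour signature, and same
#' depth-2 neighbour signature. Refinement deliberately stops at depth 2;
#' the candidate sets may over-approximate true chemical equivalence, but
#' correctness of the final mapping is guaranteed because the downstream
#' search enforces full bond consistency. Candidates are ordered by
#' template file order.
#'
#' @param query,template `molgraph` objects for which [validate_pair()]
#'   succeeded (after bond-type stripping, if that fallback was
#'   triggered).
#' @return A list of integer vectors (class `candidate_sets`), one per
#'   query atom. An empty set raises a `symrmsd_not_identical` error
#'   naming the offending query atom: despite matching composition the
#'   two structures cannot be the same molecule.
#' @export
#' @examples
#' b <- make_benzene()
#' lengths(compute_candidates(b, b))  # all 6: full ring symmetry
compute_candidates <- function(query, template) {
  stopifnot(inherits(query, "molgraph"), inherits(template, "molgraph"))
  qs1 <- vapply(seq_len(query$n_atoms),
                function(i) neighbor_signature(query, i, 1), "")
  ts1 <- vapply(seq_len(template$n_atoms),
                function(i) neighbor_signature(template, i, 1), "")
  qs2 <- vapply(seq_len(query$n_atoms),
                function(i) neighbor_signature(query, i, 2), "")
  ts2 <- vapply(seq_len(template$n_atoms),
                function(i) neighbor_signature(template, i, 2), "")
  qe <- tolower(query$elements)
  te <- tolower(template$elements)
  out <- vector("list", query$n_atoms)
  for (i in seq_len(query$n_atoms)) {
    cand <- which(te == qe[i] & ts1 == qs1[i] & ts2 == qs2[i])
    if (length(cand) == 0L)
      stop_symrmsd("not_identical", sprintf(
        "structures are not the same molecule: query atom %d (%s) has no chemically equivalent template atom",
        i, query$atom_names[i]))
    out[[i]] <- cand
  }
  structure(out, class = "candidate_sets")
}

#' Total number of possible atom mappings
#'
#' The size of the naive mapping state space: the exact product of the
#' candidate-set sizes, computed in arbitrary precision (a C60 self-pair
#' yields 60^60, far beyond double precision). A fully asymmetric
#' molecule gives 1.
#'
#' @param candidates a `candidate_sets` object from
#'   [compute_candidates()].
#' @return A `mapping_count` object; use `as.character()` for the exact
#'   decimal string.
#' @export
count_total_mappings <- function(candidates) {
  sizes <- lengths(candidates)
  acc <- big_from_int(1)
  for (s in sizes) acc <- big_mul_small(acc, s)
  acc
}
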