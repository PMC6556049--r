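#' Construct a molecular graph
#'
#' The core in-memory model: the heavy atoms of one ligand pose, their
#' Cartesian coordinates in Angstroms, and a symmetric bond-type table.
#' Bond types are lowercase strings following the TRIPOS convention
#' ("1", "2", "3", "am", "ar", "du", "un", "nc"); an empty string means
#' no bond. The graph need not be connected (salts and fragments are
#' allowed).
#'
#' @param elements character vector of element symbols, one per atom
#'   (case-normalized to title case, e.g. "C", "Cl").
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstroms). All values must be finite.
#' @param bonds square character matrix of bond-type strings, `""` for
#'   unbonded pairs. Must be symmetric with an empty diagonal.
#' @param name molecule name carried through to MOL2 output.
#' @param atom_names optional per-atom labels (defaults to element plus
#'   1-based index).
#'
#' @return An object of class `molgraph`: a list with elements `n_atoms`,
#'   `elements`, `coords`, `bonds`, `name`, `atom_names`.
#' @export
#' @examples
#' g <- molecular_graph(
#'   elements = c("C", "O"),
#'   coords = rbind(c(0, 0, 0), c(1.2, 0, 0)),
#'   bonds = matrix(c("", "2", "2", ""), 2, 2)
#' )
#' g$n_atoms
molecular_graph <- function(elements, coords, bonds, name = "MOL",
                            atom_names = NULL) {
  elements <- normalize_element(as.character(elements))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- length(elements)
  if (n == 0L) stop_symrmsd("empty_molecule", "molecule has no heavy atoms")
  if (!is.matrix(coords) || nrow(coords) != n || ncol(coords) != 3L)
    stop_symrmsd("bad_graph", "coords must be an n_atoms x 3 matrix")
  if (!all(is.finite(coords)))
    stop_symrmsd("bad_graph", "coordinates must be finite")
  bonds <- as.matrix(bonds)
  if (nrow(bonds) != n || ncol(bonds) != n)
    stop_symrmsd("bad_graph", "bonds must be an n_atoms x n_atoms matrix")
  bonds[is.na(bonds)] <- ""
  bonds <- matrix(tolower(as.character(bonds)), n, n)
  if (any(bonds != t(bonds)))
    stop_symrmsd("bad_graph", "bond table must be symmetric")
  if (any(diag(bonds) != ""))
    stop_symrmsd("bad_graph", "bond table diagonal must be empty")
  if (is.null(atom_names)) atom_names <- paste0(elements, seq_len(n))
  structure(
    list(n_atoms = n, elements = elements, coords = coords, bonds = bonds,
         name = as.character(name)[1], atom_names = as.character(atom_names)),
    class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  nb <- sum(x$bonds != "") / 2
  cat(sprintf("<molgraph> %s: %d heavy atoms, %d bonds\n",
              x$name, x$n_atoms, nb))
  comp <- table(x$elements)
  cat("  composition:",
      paste(names(comp), as.integer(comp), sep = "", collapse = " "), "\n")
  invisible(x)
}

# Title-case an element symbol: "C.AR" fragments never reach here; input is
# a bare symbol like "c", "CL", "Ru".
normalize_element <- function(x) {
  x <- trimws(x)
  bad <- !nzchar(x)
  if (any(bad)) stop_symrmsd("bad_graph", "element symbols must be non-empty")
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

# Classed conditions so callers (and the CLI) can map errors to exit codes.
stop_symrmsd <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("symrmsd_", class),
                                     "symrmsd_error"),
                      call = call))
}

#' Check that two graphs describe the same ligand molecule
#'
#' Succeeds iff the two poses have equal heavy-atom counts, equal element
#' multisets, and equal total bond counts. Additionally reports whether
#' the per-type bond-count multisets agree; when they do not (e.g. one
#' file uses aromatic "ar" ring bonds and the other alternating "1"/"2"
#' Kekule types), downstream code should strip bond types from both
#' graphs before searching for a mapping.
#'
#' @param query,template `molgraph` objects.
#' @return A list with `ok = TRUE` and logical `bond_types_comparable`.
#'   A mismatch in atom count, element multiset, or bond count raises a
#'   `symrmsd_not_same_molecule` error naming the first discrepancy.
#' @export
validate_pair <- function(query, template) {
  stopifnot(inherits(query, "molgraph"), inherits(template, "molgraph"))
  if (query$n_atoms != template$n_atoms)
    stop_symrmsd("not_same_molecule", sprintf(
      "not the same molecule: heavy-atom counts differ (%d vs %d)",
      query$n_atoms, template$n_atoms))
  eq <- sort(tolower(query$elements))
  et <- sort(tolower(template$elements))
  if (!identical(eq, et)) {
    d <- which(eq != et)[1]
    stop_symrmsd("not_same_molecule", sprintf(
      "not the same molecule: element multisets differ (first discrepancy: %s vs %s)",
      toupper(eq[d]), toupper(et[d])))
  }
  bq <- query$bonds[upper.tri(query$bonds)]
  bt <- template$bonds[upper.tri(template$bonds)]
  bq <- bq[nzchar(bq)]
  bt <- bt[nzchar(bt)]
  if (length(bq) != length(bt))
    stop_symrmsd("not_same_molecule", sprintf(
      "not the same molecule: bond counts differ (%d vs %d)",
      length(bq), length(bt)))
  comparable <- identical(sort(bq), sort(bt))
  list(ok = TRUE, bond_types_comparable = comparable)
}

#' Strip bond types, preserving topology
#'
#' Replaces every bond-type string by the generic token `"un"` so that
#' only connectivity matters. Applied to both poses when their bond-type
#' multisets disagree (files written by different programs often differ
#' in aromatic-bond conventions). Idempotent; the adjacency pattern is
#' unchanged.
#'
#' @param graph a `molgraph`.
#' @return A `molgraph` with all bonds of type `"un"`.
#' @export
strip_bond_types <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  graph$bonds[graph$bonds != ""] <- "un"
  graph
}
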