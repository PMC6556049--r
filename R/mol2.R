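#' Read a TRIPOS MOL2 file into a heavy-atom molecular graph
#'
#' Parses the MOLECULE, ATOM and BOND sections of the first molecule in
#' the source. Hydrogens (element H or D) and all bonds incident to them
#' are removed; the remaining heavy atoms are re-indexed contiguously in
#' file order. The element of each atom is taken as the SYBYL atom-type
#' substring before the first `.` ("C.ar" -> "C", "N.am" -> "N", bare
#' "Cl" -> "Cl"), case-normalized. Bond types are stored verbatim as
#' lowercase strings. Sections after BOND (SUBSTRUCTURE etc.) are
#' ignored, as is any second molecule (with a warning): the tool's
#' contract is one pose per file.
#'
#' @param source path to a MOL2 file, or a character vector of lines.
#' @return A [molecular_graph()] over the heavy atoms.
#' @export
#' @examples
#' lines <- write_mol2(make_benzene(), name = "benzene")
#' g <- read_mol2(lines)
#' g$n_atoms  # 6
read_mol2 <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
  lines <- sub("\r$", "", lines)
  sec <- grep("^@<TRIPOS>", lines)
  sec_names <- sub("^@<TRIPOS>", "", trimws(lines[sec]))
  for (need in c("MOLECULE", "ATOM", "BOND")) {
    if (!need %in% sec_names)
      stop_symrmsd("parse", sprintf("MOL2 parse error: missing @<TRIPOS>%s section", need))
  }
  # first molecule only
  mol_starts <- sec[sec_names == "MOLECULE"]
  if (length(mol_starts) > 1L) {
    warning("MOL2 source contains multiple molecules; reading the first only")
    keep <- seq_len(mol_starts[2] - 1L)
    lines <- lines[keep]
    sec <- grep("^@<TRIPOS>", lines)
    sec_names <- sub("^@<TRIPOS>", "", trimws(lines[sec]))
  }
  section_body <- function(nm) {
    i <- sec[sec_names == nm][1]
    if (is.na(i)) stop_symrmsd("parse", sprintf("MOL2 parse error: missing @<TRIPOS>%s section", nm))
    end <- c(sec, length(lines) + 1L)
    end <- min(end[end > i]) - 1L
    body <- lines[seq(i + 1L, length.out = max(0L, end - i))]
    body[nzchar(trimws(body)) & !grepl("^\\s*#", body)]
  }

  mol_body <- section_body("MOLECULE")
  mol_name <- if (length(mol_body)) trimws(mol_body[1]) else "MOL"
  if (!nzchar(mol_name)) mol_name <- "MOL"

  atom_body <- section_body("ATOM")
  if (!length(atom_body))
    stop_symrmsd("parse", "MOL2 parse error: @<TRIPOS>ATOM section is empty")
  atom_tok <- lapply(atom_body, function(l) strsplit(trimws(l), "\\s+")[[1]])
  short <- vapply(atom_tok, length, 1L) < 6L
  if (any(short))
    stop_symrmsd("parse", sprintf(
      "MOL2 parse error: ATOM line %d has fewer than 6 fields", which(short)[1]))
  atom_id <- vapply(atom_tok, function(t) suppressWarnings(as.integer(t[1])), 1L)
  xyz <- t(vapply(atom_tok,
                  function(t) suppressWarnings(as.numeric(t[3:5])), numeric(3)))
  if (anyNA(atom_id) || anyNA(xyz))
    stop_symrmsd("parse", "MOL2 parse error: malformed ATOM line")
  if (anyDuplicated(atom_id))
    stop_symrmsd("parse", "MOL2 parse error: duplicate atom ids in ATOM section")
  atom_name <- vapply(atom_tok, function(t) t[2], "")
  sybyl <- vapply(atom_tok, function(t) t[6], "")
  element <- normalize_element(sub("\\..*$", "", sybyl))

  bond_body <- section_body("BOND")
  bond_tok <- lapply(bond_body, function(l) strsplit(trimws(l), "\\s+")[[1]])
  bshort <- vapply(bond_tok, length, 1L) < 4L
  if (any(bshort))
    stop_symrmsd("parse", sprintf(
      "MOL2 parse error: BOND line %d has fewer than 4 fields", which(bshort)[1]))
  borig <- vapply(bond_tok, function(t) suppressWarnings(as.integer(t[2])), 1L)
  btarg <- vapply(bond_tok, function(t) suppressWarnings(as.integer(t[3])), 1L)
  btype <- tolower(vapply(bond_tok, function(t) t[4], ""))
  if (anyNA(borig) || anyNA(btarg))
    stop_symrmsd("parse", "MOL2 parse error: malformed BOND line")
  unknown <- !(borig %in% atom_id) | !(btarg %in% atom_id)
  if (any(unknown))
    stop_symrmsd("parse", sprintf(
      "MOL2 parse error: bond references unknown atom id %d",
      c(borig, btarg)[!(c(borig, btarg) %in% atom_id)][1]))
  if (any(borig == btarg))
    stop_symrmsd("parse", "MOL2 parse error: bond connects an atom to itself")

  heavy <- !(element %in% c("H", "D"))
  if (!any(heavy))
    stop_symrmsd("empty_molecule", "molecule has no heavy atoms")
  # re-index heavy atoms contiguously, preserving file order
  new_index <- integer(length(atom_id))
  names(new_index) <- as.character(atom_id)
  new_index[as.character(atom_id[heavy])] <- seq_len(sum(heavy))
  n <- sum(heavy)
  bonds <- matrix("", n, n)
  for (k in seq_along(borig)) {
    i <- new_index[as.character(borig[k])]
    j <- new_index[as.character(btarg[k])]
    if (i == 0L || j == 0L) next  # bond to a stripped hydrogen
    bonds[i, j] <- btype[k]
    bonds[j, i] <- btype[k]
  }
  molecular_graph(elements = element[heavy], coords = xyz[heavy, , drop = FALSE],
                  bonds = bonds, name = mol_name,
                  atom_names = atom_name[heavy])
}

#' Write a molecular graph as MOL2 text
#'
#' Emits a minimal TRIPOS MOL2 record (MOLECULE/ATOM/BOND) parseable by
#' [read_mol2()]. Coordinates are written with 4 decimal places; atom and
#' bond ids are 1-based. The SYBYL atom type is the bare element symbol.
#'
#' @param graph a non-empty `molgraph`.
#' @param name molecule name for the MOLECULE section (defaults to
#'   `graph$name`).
#' @param path optional file path; when given, lines are also written
#'   there.
#' @return Invisibly (when `path` is given) or visibly, the character
#'   vector of MOL2 lines.
#' @export
write_mol2 <- function(graph, name = graph$name, path = NULL) {
  stopifnot(inherits(graph, "molgraph"))
  n <- graph$n_atoms
  ut <- which(upper.tri(graph$bonds) & graph$bonds != "", arr.ind = TRUE)
  nb <- nrow(ut)
  lines <- c(
    "@<TRIPOS>MOLECULE",
    name,
    sprintf("%5d %5d %5d", n, nb, 0L),
    "SMALL",
    "NO_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %10.4f",
            seq_len(n), graph$atom_names,
            graph$coords[, 1], graph$coords[, 2], graph$coords[, 3],
            graph$elements, 1L, "LIG1", 0))
  if (nb > 0) {
    lines <- c(lines, "@<TRIPOS>BOND",
               sprintf("%6d %5d %5d %s", seq_len(nb),
                       ut[, 1], ut[, 2],
                       graph$bonds[ut]))
  } else {
    lines <- c(lines, "@<TRIPOS>BOND")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
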