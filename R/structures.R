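#' Molecular structure container
#'
#' A `mol_structure` is a light container for an ordered set of atoms:
#' a data frame with columns `element`, `atom_name`, `chain_id`,
#' `residue_id`, `x`, `y`, `z` (angstrom) and `mass` (amu), plus a label.
#' Atom order is stable and index-addressable; spring networks and
#' Hessians refer to atoms by row index.
#'
#' @param atoms data frame with the columns listed above (mass may be `NA`
#'   until [assign_masses()] is called).
#' @param label free-text label, e.g. `"CNT(6,6)"` or `"globule"`.
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, label = "structure") {
  required <- c("element", "atom_name", "chain_id", "residue_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"mass" %in% names(atoms)) atoms$mass <- NA_real_
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  if (any(!is.na(atoms$mass) & atoms$mass <= 0)) stop("assigned masses must be > 0")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("mol_structure '", x$label, "': ", nrow(x$atoms), " atoms, elements: ",
      paste(sort(unique(x$atoms$element)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `mol_structure`
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinate matrix of a structure
#'
#' @param s a `mol_structure`
#' @return numeric n x 3 matrix in angstrom.
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @rdname coords
#' @param value replacement n x 3 coordinate matrix.
#' @export
`coords<-` <- function(s, value) {
  stopifnot(nrow(value) == nrow(s$atoms), ncol(value) == 3)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

# Standard atomic weights (amu), CIAAW conventional values; D = deuterium.
.atomic_weights <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  FE = 55.845, ZN = 65.38, CU = 63.546, MN = 54.938, MG = 24.305,
  CA = 40.078, K = 39.098, SE = 78.971, NI = 58.693, CO = 58.933,
  MO = 95.95, B = 10.81, SI = 28.085, AL = 26.982, LI = 6.94,
  "NA" = 22.990
)

# Two-letter element symbols recognised when inferring elements from
# PDB atom names with a blank element column. "CA" is deliberately
# absent: in ATOM records it is almost always an alpha carbon, and
# calcium ions normally carry an explicit element column.
.two_letter_elements <- c("FE", "CL", "BR", "ZN", "MG", "MN", "NA",
                          "CU", "NI", "CO", "SE", "MO", "SI", "AL", "LI")

#' Infer element symbols from PDB atom names
#'
#' Fallback used when the PDB element column is blank: the first
#' alphabetic character of the atom name, except for a recognised
#' two-letter symbol list (FE, CL, ZN, ...).
#'
#' @param atom_name character vector of PDB atom names.
#' @return character vector of element symbols (upper case).
#' @export
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", atom_name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% .two_letter_elements, two, substr(nm, 1, 1))
}

#' Read a molecular structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model (multi-model files are
#' trajectory input; see [read_trajectory_pdb()]). Elements come from the
#' PDB element column when present, otherwise they are inferred from the
#' atom name via [infer_element()]. Masses are left unassigned; call
#' [assign_masses()] before building a network.
#'
#' @param path path to a PDB file.
#' @param label label for the returned structure; defaults to the file name.
#' @return a [mol_structure()].
#' @export
read_pdb <- function(path, label = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ", conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  if (any(blank)) elem[blank] <- infer_element(at$elety[blank])
  atoms <- data.frame(
    element = elem,
    atom_name = trimws(at$elety),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    residue_id = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    mass = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
    stop("non-finite coordinates at atom record(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  mol_structure(atoms, label = if (is.null(label)) basename(path) else label)
}

#' Write a structure to a PDB file
#'
#' Coordinates must fit the fixed-width PDB coordinate fields
#' (|x| < 10000 angstrom); a round trip through [read_pdb()] reproduces
#' elements and coordinates to 3 decimals.
#'
#' @param s a `mol_structure`
#' @param path output path
#' @export
write_pdb <- function(s, path) {
  xyz <- coords(s)
  if (any(abs(xyz) >= 10000)) {
    stop("coordinate magnitude >= 10000 angstrom does not fit PDB fields")
  }
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", nrow(a)),
    resno = a$residue_id,
    resid = rep("MOL", nrow(a)),
    eleno = seq_len(nrow(a)),
    elety = a$atom_name,
    chain = a$chain_id,
    elesy = a$element
  )
  invisible(path)
}

#' Remove hydrogen (and deuterium) atoms
#'
#' The elastic network is built over heavy atoms only; this drops every
#' atom whose element is H or D, preserving the order of the survivors.
#' Idempotent.
#'
#' @param s a `mol_structure`
#' @return a `mol_structure` without hydrogens.
#' @export
strip_hydrogens <- function(s) {
  keep <- !(toupper(s$atoms$element) %in% c("H", "D"))
  if (!any(keep)) warning("structure contains only hydrogens; result is empty")
  out <- s
  out$atoms <- s$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Assign atomic masses from a lookup table
#'
#' @param s a `mol_structure`
#' @param table named numeric vector element -> amu; defaults to standard
#'   atomic weights.
#' @return the structure with the `mass` column filled.
#' @export
assign_masses <- function(s, table = NULL) {
  tab <- if (is.null(table)) .atomic_weights else table
  el <- toupper(s$atoms$element)
  unknown <- setdiff(unique(el), names(tab))
  if (length(unknown)) {
    stop("no mass for element(s): ", paste(unknown, collapse = ", "))
  }
  s$atoms$mass <- unname(tab[el])
  s
}

#' Combine two structures into one
#'
#' Atom order is the first structure's atoms followed by the second's.
#' Useful for enzyme-plus-surface systems; the returned attribute
#' `"block_sizes"` records the split.
#'
#' @param a,b `mol_structure` objects
#' @param label label of the combined structure
#' @export
combine_structures <- function(a, b, label = paste(a$label, b$label, sep = "+")) {
  out <- mol_structure(rbind(a$atoms, b$atoms), label = label)
  attr(out, "block_sizes") <- c(n_atoms(a), n_atoms(b))
  out
}
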