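# Molecular coordinate container used by the forward model and the
# samplers.  Two flavours share one class: atomic models read from PDB
# files, and coarse-grained bead models (one scatterer per bead/residue)
# built by the synthetic-system generator.  Every atom belongs to exactly
# one rigid group (id >= 1) or to the flexible set (id 0).

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Construct a molecule
#'
#' @param atoms data frame with columns `element`, `resid` (integer),
#'   `resname`, `atom` (atom name) and `chain`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param rigid_group integer per atom: 0 = flexible, >= 1 = rigid-group id.
#' @param bead logical; `TRUE` marks a coarse-grained bead model whose
#'   scattering is described by per-atom columns `f0` (effective electron
#'   count), `volume` (displaced solvent volume, cubic Angstrom) and
#'   `radius` (bead radius, Angstrom) in `atoms`.
#' @return object of class `saxs_molecule`.
#' @export
saxs_molecule <- function(atoms, xyz, rigid_group = NULL, bead = FALSE) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3 || nrow(xyz) != nrow(atoms))
    stop("xyz must be an n_atoms x 3 matrix")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(rigid_group)) rigid_group <- rep(0L, nrow(atoms))
  if (length(rigid_group) != nrow(atoms))
    stop("rigid_group must have one entry per atom")
  if (bead && !all(c("f0", "volume", "radius") %in% names(atoms)))
    stop("bead models need f0, volume and radius columns")
  structure(list(atoms = atoms, xyz = xyz,
                 rigid_group = as.integer(rigid_group), bead = bead),
            class = "saxs_molecule")
}

#' Number of atoms in a molecule
#' @param mol a [saxs_molecule].
#' @export
n_atoms <- function(mol) nrow(mol$xyz)

#' Center of mass (unweighted centroid) of a molecule or atom subset
#' @param mol a [saxs_molecule].
#' @param idx optional atom indices.
#' @export
mol_com <- function(mol, idx = NULL) {
  if (is.null(idx)) colMeans(mol$xyz) else colMeans(mol$xyz[idx, , drop = FALSE])
}

#' Extract an atom subset as a new molecule
#' @param mol a [saxs_molecule].
#' @param idx atom indices to keep.
#' @export
subset_molecule <- function(mol, idx) {
  saxs_molecule(mol$atoms[idx, , drop = FALSE],
                mol$xyz[idx, , drop = FALSE],
                mol$rigid_group[idx], bead = mol$bead)
}

# van der Waals radius per atom (bead models carry their own).
atom_radii <- function(mol) {
  if (mol$bead) return(mol$atoms$radius)
  r <- VDW_RADII[mol$atoms$element]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' @export
print.saxs_molecule <- function(x, ...) {
  ng <- length(setdiff(unique(x$rigid_group), 0L))
  cat(sprintf("%s model: %d atoms, %d residues, %d rigid group(s), %d flexible atom(s)\n",
              if (x$bead) "Bead" else "Atomic", n_atoms(x),
              length(unique(x$atoms$resid)), ng, sum(x$rigid_group == 0L)))
  invisible(x)
}

# element inferred from a PDB atom name: first letter that is not a digit,
# with two-letter check against the known table (handles " CA " vs "CA"
# calcium ambiguity conservatively in favour of carbon for protein atoms).
infer_element <- function(atom_name) {
  nm <- gsub("[0-9'\\s]", "", atom_name)
  one <- toupper(substr(nm, 1, 1))
  ifelse(one %in% names(VDW_RADII), one, "C")
}

#' Read a PDB file into a molecule
#'
#' ATOM and HETATM records are read (via \pkg{bio3d}); for atoms with
#' alternate locations only the first altloc is kept; a missing element
#' field is inferred from the atom name.  All atoms are placed in rigid
#' group 1; use [rigid_system()] or edit `rigid_group` to partition.
#'
#' @param path PDB file path.
#' @return a [saxs_molecule].
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0) stop("no ATOM/HETATM records in ", path)
  # keep first altloc per (chain, resid, atom name)
  key <- paste(a$chain, a$resno, a$elety)
  a <- a[!duplicated(key), , drop = FALSE]
  elem <- a$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  elem[bad] <- infer_element(a$elety[bad])
  elem <- toupper(trimws(elem))
  atoms <- data.frame(element = elem,
                      resid = as.integer(a$resno),
                      resname = trimws(a$resid),
                      atom = trimws(a$elety),
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      stringsAsFactors = FALSE)
  xyz <- cbind(a$x, a$y, a$z)
  saxs_molecule(atoms, xyz, rigid_group = rep(1L, nrow(atoms)))
}

#' Write a molecule to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals).
#'
#' @param mol a [saxs_molecule].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(mol, path) {
  stopifnot(inherits(mol, "saxs_molecule"))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(mol$xyz)),
                   resno = mol$atoms$resid,
                   resid = mol$atoms$resname,
                   eleno = seq_len(n_atoms(mol)),
                   elety = mol$atoms$atom,
                   chain = mol$atoms$chain,
                   elesy = mol$atoms$element)
  invisible(path)
}
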