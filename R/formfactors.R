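# Atomic X-ray form factors for the Debye forward model.
#
# Vacuum factors use the standard 4-Gaussian-plus-constant Cromer-Mann
# parameterization, f_vac(q) = sum_k a_k exp(-b_k (q/4pi)^2) + c, adequate to
# well beyond the q < 0.5 A^-1 range relevant to SAXS.  The excluded-volume
# (dummy-atom) term is the Gaussian sphere of the element's displaced solvent
# volume, f_dummy(q) = rho0 * V * exp(-q^2 V^(2/3) / (4 pi)), with bulk water
# electron density rho0 = 0.334 e/A^3 (Fraser/Svergun convention).  The
# excluded-volume scaling parameter c1 multiplies the dummy term by
# c1^3 * exp(-(4 pi/3)^(3/2) q^2 r_m^2 (c1^2 - 1) / (4 pi)), r_m being the
# mean dummy-atom radius of the molecule.

RHO_SOLVENT <- 0.334  # bulk water electron density, e / A^3

CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490)
)

# displaced solvent volumes, A^3 (Fraser et al. 1978)
DISPLACED_VOLUME <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13,
                      S = 19.86, P = 5.73)

#' Form-factor table
#'
#' Returns the per-element scattering parameters used by the forward model:
#' Cromer-Mann vacuum coefficients (`a`, `b`, `c`), the displaced solvent
#' volume `volume` (cubic Angstrom) and the derived dummy-atom radius
#' `radius` (Angstrom).
#'
#' @return named list, one entry per supported element.
#' @export
form_factor_table <- function() {
  lapply(stats::setNames(nm = names(CROMER_MANN)), function(el) {
    v <- DISPLACED_VOLUME[[el]]
    c(CROMER_MANN[[el]], list(volume = v, radius = (3 * v / (4 * pi))^(1 / 3)))
  })
}

# vacuum form factor of one element on a q vector
f_vacuum <- function(element, q) {
  p <- CROMER_MANN[[element]]
  if (is.null(p)) stop("unknown element: ", element)
  s2 <- (q / (4 * pi))^2
  f <- rep(p$c, length(q))
  for (k in 1:4) f <- f + p$a[k] * exp(-p$b[k] * s2)
  f
}

# Gaussian-sphere dummy (excluded volume) factor for a displaced volume V
f_dummy_volume <- function(V, q) {
  RHO_SOLVENT * V * exp(-q^2 * V^(2 / 3) / (4 * pi))
}

# c1 radius-scaling factor applied to the dummy term; r_m is the mean
# dummy-atom radius of the molecule.
c1_scaling <- function(q, c1, r_m) {
  c1^3 * exp(-(4 * pi / 3)^(3 / 2) * q^2 * r_m^2 * (c1^2 - 1) / (4 * pi))
}

# water form factor (vacuum O + 2 H), used for the hydration layer term
f_water <- function(q) f_vacuum("O", q) + 2 * f_vacuum("H", q)

#' Effective (solvent-corrected) atomic form factor
#'
#' `f(q) = f_vac(q) - f_dummy(q) * c1^3 exp(-(4pi/3)^{3/2} q^2 r_m^2 (c1^2-1)/(4pi))`,
#' the in-solution contrast of a single atom: vacuum scattering minus the
#' excluded-volume (dummy-atom) term, whose magnitude the parameter `c1`
#' adjusts through an effective atomic-radius scaling.  Optionally the
#' scattering of `n_h` implicit (bonded) hydrogens is folded in, adding both
#' their vacuum factors and their displaced volumes.
#'
#' @param element element symbol (H, C, N, O, S, P).
#' @param q momentum transfer vector, inverse Angstrom, `>= 0`.
#' @param c1 excluded-volume scaling in `[0.95, 1.05]`.
#' @param r_m mean dummy-atom radius of the molecule (Angstrom); the default
#'   1.62 is typical of protein heavy atoms.
#' @param n_h implicit hydrogens folded into this atom.
#' @return numeric vector of amplitudes, one per q.
#' @export
effective_form_factor <- function(element, q, c1 = 1, r_m = 1.62, n_h = 0) {
  if (!element %in% names(CROMER_MANN)) stop("unknown element: ", element)
  if (any(q < 0)) stop("q must be nonnegative")
  fv <- f_vacuum(element, q) + n_h * f_vacuum("H", q)
  V <- DISPLACED_VOLUME[[element]] + n_h * DISPLACED_VOLUME[["H"]]
  fv - f_dummy_volume(V, q) * c1_scaling(q, c1, r_m)
}

# Implicit-hydrogen counts for standard protein heavy-atom names.  A
# name-based heuristic (with residue-specific overrides where the count is
# ambiguous); atoms not listed get 0 and scatter as the bare element.
implicit_hydrogens <- function(atom, resname) {
  n <- integer(length(atom))
  base <- c(N = 1L, CA = 1L, CB = 2L, CG = 2L, CG1 = 2L, CG2 = 3L,
            CD = 2L, CD1 = 1L, CD2 = 1L, CE = 2L, CE1 = 1L, CE2 = 1L,
            CE3 = 1L, CZ = 0L, CZ2 = 1L, CZ3 = 1L, CH2 = 1L,
            NE = 1L, NH1 = 2L, NH2 = 2L, NZ = 3L, ND1 = 1L, ND2 = 2L,
            NE1 = 1L, NE2 = 2L, OG = 1L, OG1 = 1L, OH = 1L, SG = 1L)
  hit <- atom %in% names(base)
  n[hit] <- base[atom[hit]]
  n[atom == "CA" & resname == "GLY"] <- 2L
  n[atom == "CB" & resname == "ALA"] <- 3L
  n[atom == "CB" & resname %in% c("ILE", "THR", "VAL")] <- 1L
  n[atom == "CG" & resname == "LEU"] <- 1L
  n[atom == "CG" & resname %in% c("ASN", "ASP", "HIS", "PHE", "TRP", "TYR")] <- 0L
  n[atom == "CD" & resname %in% c("GLN", "GLU")] <- 0L
  n[atom %in% c("CD1", "CD2") & resname == "LEU"] <- 3L
  n[atom == "CD1" & resname == "ILE"] <- 3L
  n[atom == "CE" & resname == "MET"] <- 3L
  n[atom == "N" & resname == "PRO"] <- 0L
  n
}

# Per-atom form-factor matrix, length(q) x n_atoms, for the full corrected
# model: contrast term plus c2-scaled hydration-shell water factor weighted
# by the atom's solvent exposure.  hyd_w may be NULL when c2 == 0.
form_factor_matrix <- function(mol, q, c1 = 1, c2 = 0, hyd_w = NULL,
                               components = FALSE) {
  nq <- length(q); na <- n_atoms(mol)
  if (mol$bead) {
    Fv <- matrix(rep(mol$atoms$f0, each = nq), nq, na)
    V <- mol$atoms$volume
    r_m <- mean((3 * V / (4 * pi))^(1 / 3))
    Fd <- vapply(V, f_dummy_volume, numeric(nq), q = q) * c1_scaling(q, c1, r_m)
  } else {
    nh <- implicit_hydrogens(mol$atoms$atom, mol$atoms$resname)
    elem <- mol$atoms$element
    Fv <- matrix(0, nq, na)
    for (el in unique(elem)) {
      i <- which(elem == el)
      Fv[, i] <- f_vacuum(el, q)
    }
    Fv <- Fv + outer(f_vacuum("H", q), nh)
    V <- DISPLACED_VOLUME[elem] + nh * DISPLACED_VOLUME[["H"]]
    V[is.na(V)] <- DISPLACED_VOLUME[["C"]]
    r_m <- mean((3 * V / (4 * pi))^(1 / 3))
    Fd <- vapply(V, f_dummy_volume, numeric(nq), q = q) * c1_scaling(q, c1, r_m)
  }
  Fc <- Fv - Fd                      # in-solution contrast
  if (c2 != 0) {
    if (is.null(hyd_w)) stop("hydration weights required when c2 != 0")
    Fh <- outer(f_water(q), c2 * hyd_w)
  } else {
    Fh <- matrix(0, nq, na)
  }
  if (components) list(contrast = Fc, hydration = Fh) else Fc + Fh
}
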