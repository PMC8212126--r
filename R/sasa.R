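# Solvent-accessible surface fractions (Shrake-Rupley) driving the
# hydration-layer term of the forward model.

# Deterministic, near-uniform unit-sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-exposure weights for the hydration layer
#'
#' Shrake-Rupley fraction of each atom's solvent-accessible surface (probe
#' radius 1.8 Angstrom, the convention of FoXS-style hydration terms),
#' normalized to `[0, 1]`: 1 for a fully exposed atom, 0 for a buried one.
#' These weights multiply the water form factor and the hydration-density
#' parameter c2 in the forward model.
#'
#' @param mol a [saxs_molecule].
#' @param probe probe radius, Angstrom.
#' @param n_points test points per atomic sphere (speed/accuracy trade-off).
#' @return numeric vector in `[0, 1]`, one weight per atom.
#' @export
hydration_surface_weights <- function(mol, probe = 1.8, n_points = 64) {
  n <- n_atoms(mol)
  if (n == 0) stop("empty molecule")
  rad <- atom_radii(mol) + probe
  xyz <- mol$xyz
  pts <- sphere_points(n_points)
  D2 <- as.matrix(stats::dist(xyz))^2
  w <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) { w[i] <- 1; next }
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(p, 2, xyz[j, ])
      free <- free & rowSums(dj^2) >= rad[j]^2
      if (!any(free)) break
    }
    w[i] <- sum(free) / n_points
  }
  w
}
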