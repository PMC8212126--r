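# Synthetic-data generators: toy two-domain bead systems and noisy
# synthetic profiles.  These define the study conditions under which every
# sampling and selection stage is exercised offline; all randomness is
# seeded and reproducible.

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic two-domain bead system
#'
#' The generated system emulates a two-domain protein at one bead per
#' residue: two compact bead clusters of distinct sizes (so the relative
#' pose is identifiable from scattering), optionally joined by a flexible
#' bead linker.
#'
#' @param beads integer(2), beads per domain.
#' @param radii numeric(2), domain sphere radii in Angstrom.
#' @param linker number of flexible linker beads between the domains.
#' @param separation inter-domain center-of-mass distance, Angstrom.
#' @param bead_f0 effective electron count per bead (glycine-residue scale).
#' @param bead_volume displaced solvent volume per bead, cubic Angstrom.
#' @param bead_radius bead collision/SASA radius, Angstrom; the default is
#'   half the C-alpha virtual-bond distance (3.86 / 2), the convention the
#'   linker builder uses for C-alpha excluded volume.
#' @param seed RNG seed.
#' @return list of class `two_domain_spec`.
#' @export
two_domain_spec <- function(beads = c(14, 8), radii = c(8, 6), linker = 0,
                            separation = 28, bead_f0 = 50, bead_volume = 100,
                            bead_radius = 1.93, seed = 1) {
  stopifnot(all(beads >= 1), all(radii > 0), linker >= 0, separation > 0,
            bead_f0 > 0, bead_volume > 0, bead_radius > 0)
  structure(list(beads = as.integer(beads), radii = radii,
                 linker = as.integer(linker), separation = separation,
                 bead_f0 = bead_f0, bead_volume = bead_volume,
                 bead_radius = bead_radius, seed = as.integer(seed)),
            class = "two_domain_spec")
}

# n points roughly uniform in a sphere of given radius, re-centred exactly
ball_cloud <- function(n, radius) {
  p <- matrix(stats::rnorm(3 * n), n, 3)
  r <- radius * stats::runif(n)^(1 / 3)
  p <- p / sqrt(rowSums(p^2)) * r
  sweep(p, 2, colMeans(p))
}

#' Generate a synthetic two-domain bead molecule
#'
#' Domain 1 (rigid group 1) is centred at the origin, domain 2 (rigid group
#' 2) at `(separation, 0, 0)`; linker beads (flexible, group 0) are placed
#' on the connecting line.  Deterministic per seed.
#'
#' @param spec a [two_domain_spec].
#' @return a bead-mode [saxs_molecule].
#' @export
make_two_domain_system <- function(spec) {
  stopifnot(inherits(spec, "two_domain_spec"))
  with_seed(spec$seed, {
    a <- ball_cloud(spec$beads[1], spec$radii[1])
    b <- ball_cloud(spec$beads[2], spec$radii[2])
  })
  b <- sweep(b, 2, c(spec$separation, 0, 0), `+`)
  xyz <- rbind(a, b)
  n <- nrow(xyz)
  grp <- c(rep(1L, spec$beads[1]), rep(2L, spec$beads[2]))
  atoms <- data.frame(element = "C", resid = seq_len(n), resname = "BEA",
                      atom = "CA", chain = "A",
                      f0 = spec$bead_f0, volume = spec$bead_volume,
                      radius = spec$bead_radius, stringsAsFactors = FALSE)
  mol <- saxs_molecule(atoms, xyz, rigid_group = grp, bead = TRUE)
  # the linker is built with the same C-alpha path construction the
  # structure-determination stages use, so generated systems are
  # geometrically consistent with the linker model (ideal virtual-bond
  # spacing, no clashes)
  if (spec$linker > 0) mol <- add_bead_linker(mol, spec$linker,
                                              seed = spec$seed)
  mol
}

#' Noise model for synthetic profiles
#'
#' Per-point uncertainty `s(q) = a * I(q) + b` with `b = b_frac * I(0)`,
#' and Gaussian noise of standard deviation `s(q)` added to the clean
#' intensities.  The defaults keep the expected chi-square of the
#' generating structure at 1, so the error-scale estimate sigma-hat ~ 1 is
#' the recovery target.
#'
#' @param a relative error slope.
#' @param b_frac additive floor as a fraction of I(0).
#' @param seed RNG seed for the noise draw.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(a = 0.01, b_frac = 1e-4, seed = 1) {
  stopifnot(a >= 0, b_frac >= 0, a + b_frac > 0)
  structure(list(a = a, b_frac = b_frac, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a noisy experimental profile from a structure
#'
#' Computes `gamma_true * m(X, q, c1, c2)` and attaches errors
#' `s(q) = a I + b`; with `perturb = TRUE` (default) Gaussian noise of sd
#' `s(q)` is added, giving data whose chi-square against the generating
#' structure is ~1 by construction.
#'
#' @param mol a [saxs_molecule].
#' @param q q grid, inverse Angstrom.
#' @param gamma_true true scale factor.
#' @param c1,c2 forward-model parameters used in generation.
#' @param noise a [noise_spec].
#' @param perturb add the Gaussian noise (set `FALSE` for noise-free data
#'   with the same error column).
#' @return a [saxs_profile]; the generating parameters are recorded in
#'   `attr(, "truth")`.
#' @export
simulate_profile <- function(mol, q, gamma_true = 1, c1 = 1, c2 = 0,
                             noise = noise_spec(), perturb = TRUE) {
  stopifnot(inherits(noise, "noise_spec"))
  m <- compute_profile(mol, q, c1 = c1, c2 = c2)$intensity
  clean <- gamma_true * m
  s <- noise$a * abs(clean) + noise$b_frac * abs(clean[1])
  I <- if (perturb) {
    with_seed(noise$seed, clean + stats::rnorm(length(q), 0, s))
  } else clean
  out <- saxs_profile(q, I, s, label = "synthetic")
  attr(out, "truth") <- list(gamma = gamma_true, c1 = c1, c2 = c2,
                             seed = noise$seed, perturbed = perturb)
  out
}

#' Pool of per-conformer profiles with a planted experimental mixture
#'
#' Builds the input of the ensemble-selection stage: one computed profile
#' per conformer on a common q grid, plus an "experimental" profile formed
#' as the stated weighted mixture of the conformer profiles with noise.
#' The generating weights are recorded for recovery tests.
#'
#' @param mols list of [saxs_molecule] conformers.
#' @param weights mixture weights (nonnegative, summing to 1) of the
#'   planted experimental ensemble.
#' @param q common q grid.
#' @param noise a [noise_spec] for the experimental profile.
#' @param c1,c2 forward-model parameters.
#' @return object of class `profile_pool`: list with `ids`, `intensities`
#'   (matrix, one column per conformer), `exp` (a [saxs_profile]) and
#'   `truth` (the planted weights).
#' @export
make_profile_pool <- function(mols, weights, q, noise = noise_spec(),
                              c1 = 1, c2 = 0) {
  stopifnot(length(mols) == length(weights), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  Im <- vapply(mols, function(m) compute_profile(m, q, c1 = c1, c2 = c2)$intensity,
               numeric(length(q)))
  clean <- drop(Im %*% weights)
  s <- noise$a * abs(clean) + noise$b_frac * abs(clean[1])
  I <- with_seed(noise$seed, clean + stats::rnorm(length(q), 0, s))
  profile_pool(Im, saxs_profile(q, I, s, label = "synthetic mixture"),
               truth = weights)
}

#' Construct a profile pool
#'
#' @param intensities matrix of computed intensities, one column per
#'   conformer, rows matching `exp$q`.
#' @param exp experimental [saxs_profile] on the same grid.
#' @param ids conformer identifiers (default column index).
#' @param truth optional planted mixture weights (bookkeeping for tests).
#' @return object of class `profile_pool`.
#' @export
profile_pool <- function(intensities, exp, ids = NULL, truth = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(inherits(exp, "saxs_profile"), nrow(intensities) == nrow(exp))
  if (is.null(ids)) ids <- seq_len(ncol(intensities))
  if (anyDuplicated(ids)) stop("conformer ids must be unique")
  structure(list(ids = ids, intensities = intensities, exp = exp,
                 truth = truth),
            class = "profile_pool")
}

#' @export
print.profile_pool <- function(x, ...) {
  cat(sprintf("Profile pool: %d conformers x %d q-points%s\n",
              ncol(x$intensities), nrow(x$intensities),
              if (!is.null(x$truth)) " (planted mixture recorded)" else ""))
  invisible(x)
}
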