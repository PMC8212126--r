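# Score-driven Monte Carlo: rigid-body docking of one domain around
# another and dihedral refinement of flexible segments, under an energy
# built from the Bayesian SAXS restraint (or a fixed-weight chi-square
# term) plus a quadratic excluded-volume penalty.  Nuisance parameters are
# refreshed deterministically to their maximum-posterior values between
# Metropolis move blocks, which makes the restraint weight self-adjusting.

# ---- excluded volume ------------------------------------------------------

# pair mask: TRUE for pairs that count toward the clash penalty
# (upper triangle, different rigid groups or at least one flexible atom,
# non-adjacent residues on the same chain)
clash_pair_mask <- function(mol) {
  n <- n_atoms(mol)
  g <- mol$rigid_group
  same_group <- outer(g, g, `==`) & outer(g, g, function(a, b) a > 0)
  adjacent <- abs(outer(mol$atoms$resid, mol$atoms$resid, `-`)) <= 1 &
    outer(mol$atoms$chain, mol$atoms$chain, `==`)
  upper.tri(matrix(0, n, n)) & !same_group & !adjacent
}

#' Quadratic excluded-volume penalty
#'
#' `sum over clashing pairs of k (r_i + r_j - d_ij)^2` for pairs with
#' `d_ij < r_i + r_j`.  Pairs within the same rigid body and covalently
#' adjacent residues (|delta resid| <= 1 on one chain) are excluded.
#'
#' @param mol a [saxs_molecule] (bead radii or van der Waals radii).
#' @param k force constant, score units per square Angstrom.
#' @return nonnegative penalty; 0 when clash-free.
#' @export
excluded_volume <- function(mol, k = 1) {
  mask <- clash_pair_mask(mol)
  r <- atom_radii(mol)
  D <- as.matrix(stats::dist(mol$xyz))
  ov <- outer(r, r, `+`) - D
  ov[!mask | ov <= 0] <- 0
  k * sum(ov^2)
}

# ---- rigid-body system ----------------------------------------------------

#' Define a two-body (plus flexible atoms) sampling system
#'
#' @param mol a [saxs_molecule] whose `rigid_group` labels partition the
#'   atoms into the fixed body, the mobile body and the flexible set (0).
#' @param fixed_group,mobile_group rigid-group ids of the two bodies.
#' @return object of class `rigid_system`: the molecule plus index sets,
#'   reference (template) coordinates of both bodies for pose descriptors,
#'   and the rotatable-torsion list of the flexible atoms.
#' @export
rigid_system <- function(mol, fixed_group = 1, mobile_group = 2) {
  fixed <- which(mol$rigid_group == fixed_group)
  mobile <- which(mol$rigid_group == mobile_group)
  flexible <- which(mol$rigid_group == 0L)
  if (length(fixed) == 0 || length(mobile) == 0)
    stop("both bodies must be non-empty")
  if (length(intersect(fixed, mobile)) > 0) stop("bodies must be disjoint")
  structure(list(mol = mol, fixed = fixed, mobile = mobile,
                 flexible = flexible,
                 fixed_ref = mol$xyz[fixed, , drop = FALSE],
                 mobile_ref = scale(mol$xyz[mobile, , drop = FALSE],
                                    scale = FALSE),
                 torsions = flexible_torsions(mol)),
            class = "rigid_system")
}

# Rotatable torsions of the flexible chain segments.  For bead (C-alpha
# only) chains each virtual bond between consecutive chain positions is an
# axis; for atomic backbones the phi (N-CA) and psi (CA-C) bonds are used.
# Each entry: axis atom indices (a, b), the downstream atom set moved by a
# rotation about a->b, and the segment kind ("linker" between two rigid
# groups, "termini" otherwise).
flexible_torsions <- function(mol) {
  flex <- which(mol$rigid_group == 0L)
  if (length(flex) == 0) return(list())
  res <- sort(unique(mol$atoms$resid[flex]))
  segs <- split(res, cumsum(c(1, diff(res) != 1)))
  ord <- order(mol$atoms$resid)  # chain order by residue
  out <- list()
  all_res <- mol$atoms$resid
  for (sg in segs) {
    before <- any(all_res < min(sg) & mol$rigid_group > 0)
    after <- any(all_res > max(sg) & mol$rigid_group > 0)
    kind <- if (before && after) "linker" else "termini"
    is_bead <- mol$bead
    # residues spanned: include the anchor residues so the first/last
    # virtual bonds are rotatable too
    span <- seq(min(sg) - as.integer(before), max(sg) + as.integer(after))
    span <- span[span %in% all_res]
    if (is_bead) {
      idx <- vapply(span, function(r) which(all_res == r)[1], integer(1))
      for (p in seq_len(length(idx) - 1)) {
        a <- idx[p]; b <- idx[p + 1]
        if (after || before) {
          # move everything downstream (toward increasing resid); for a
          # pure N-terminal segment move the upstream free end instead
          if (!after && before) {
            moving <- which(all_res < all_res[a])
          } else {
            moving <- which(all_res > all_res[b])
            moving <- moving[mol$rigid_group[moving] == 0 |
                               all_res[moving] > max(sg)]
          }
        } else moving <- which(all_res > all_res[b])
        # never move the fixed first body
        moving <- setdiff(moving, which(mol$rigid_group == 1L))
        if (length(moving) > 0)
          out[[length(out) + 1]] <- list(a = a, b = b, moving = moving,
                                         kind = kind)
      }
    } else {
      for (r in sg) {
        ri <- which(all_res == r)
        nm <- mol$atoms$atom[ri]
        N <- ri[nm == "N"]; CA <- ri[nm == "CA"]; C <- ri[nm == "C"]
        if (length(N) == 1 && length(CA) == 1) {  # phi
          moving <- c(ri[!nm %in% c("N", "CA")], which(all_res > r))
          moving <- setdiff(moving, which(mol$rigid_group == 1L))
          out[[length(out) + 1]] <- list(a = N, b = CA, moving = moving,
                                         kind = kind)
        }
        if (length(CA) == 1 && length(C) == 1) {  # psi
          moving <- c(ri[nm == "O"], which(all_res > r))
          moving <- setdiff(moving, which(mol$rigid_group == 1L))
          out[[length(out) + 1]] <- list(a = CA, b = C, moving = moving,
                                         kind = kind)
        }
      }
    }
  }
  out
}

#' Monte Carlo run configuration
#'
#' @param n_steps number of steps; each step is `moves_per_step` Metropolis
#'   proposals followed by a nuisance-parameter update.
#' @param moves_per_step proposals per step (100 for docking, 10 for
#'   dihedral refinement by default of the respective drivers).
#' @param rot_step rigid-rotation proposal scale, radians.
#' @param trans_step translation proposal scale, Angstrom.
#' @param dihedral_std_termini,dihedral_std_linker Gaussian dihedral
#'   perturbation scales, radians.
#' @param temperature Metropolis temperature (scores are negative log
#'   probabilities; 1 by convention).
#' @param seed RNG seed, recorded in the trajectory.
#' @param weight_mode `"bayesian"` (automatic `M / 2 sigma^2`) or a fixed
#'   nonnegative numeric weight.
#' @param c1c2 when to run the c1/c2 grid search: `"step"` (before every
#'   nuisance update), `"start"` (once), `"never"` (hold at `c1`, `c2`).
#' @param c1,c2 forward-model parameters used when not optimized.
#' @param ev_k excluded-volume force constant.
#' @param stall_window steps of zero acceptance before a stall warning.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_steps = 100, moves_per_step = 100, rot_step = 0.05,
                      trans_step = 0.05, dihedral_std_termini = 5e-2,
                      dihedral_std_linker = 5e-3, temperature = 1, seed = 1,
                      weight_mode = "bayesian", c1c2 = "start", c1 = 1,
                      c2 = 0, ev_k = 1, stall_window = 100) {
  stopifnot(n_steps >= 1, moves_per_step >= 1, rot_step > 0, trans_step > 0,
            dihedral_std_termini >= 0, dihedral_std_linker >= 0,
            temperature > 0)
  if (!identical(weight_mode, "bayesian")) {
    weight_mode <- as.numeric(weight_mode)
    stopifnot(weight_mode >= 0)
  }
  c1c2 <- match.arg(c1c2, c("step", "start", "never"))
  structure(as.list(environment()), class = "mc_config")
}

metropolis_accept <- function(dE, temperature = 1) {
  dE <= 0 || log(stats::runif(1)) < -dE / temperature
}

#' Random clash-free starting pose for the mobile body
#'
#' Applies a uniformly random orientation to the mobile body and places its
#' centre of mass at a uniformly random direction on a sphere enclosing
#' both bodies (enlarged by a margin), rejecting placements until the
#' excluded-volume penalty is zero.
#'
#' @param system a [rigid_system].
#' @param seed RNG seed.
#' @param margin added to the enclosing-sphere radius, Angstrom.
#' @param max_tries rejection budget before a placement error.
#' @return the system with the mobile body repositioned.
#' @export
randomize_start <- function(system, seed = 1, margin = 2, max_tries = 1e4) {
  mol <- system$mol
  fx <- system$fixed; mb <- system$mobile
  com_f <- mol_com(mol, fx)
  r_f <- max(sqrt(rowSums(sweep(mol$xyz[fx, , drop = FALSE], 2, com_f)^2)))
  mref <- system$mobile_ref
  r_m <- max(sqrt(rowSums(mref^2)))
  rad <- r_f + r_m + margin + max(atom_radii(mol))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      R <- quat_to_mat(quat_random())
      xyz <- mol$xyz
      xyz[mb, ] <- sweep(mref %*% t(R), 2, com_f + rad * u, `+`)
      cand <- mol; cand$xyz <- xyz
      if (excluded_volume(cand) == 0) {
        system$mol <- cand
        return(system)
      }
    }
    stop("could not place mobile body clash-free in ", max_tries, " tries")
  })
}

# ---- shared Metropolis engine ---------------------------------------------

# Internal driver used by rigid_dock / dihedral_refine / fixed_weight_run.
run_mc <- function(system, profile, config, move_types) {
  mol <- system$mol
  if (!mol$bead && any(mol$atoms$element == "H"))
    stop("remove hydrogen atoms before sampling (their scattering is folded into heavy atoms)")
  q <- profile$q
  M <- nrow(profile)
  bayesian <- identical(config$weight_mode, "bayesian")
  tors <- system$torsions
  if ("dihedral" %in% move_types && length(tors) == 0)
    stop("no flexible atoms: dihedral moves impossible")

  # clash bookkeeping
  mask <- clash_pair_mask(mol)
  rsum <- outer(atom_radii(mol), atom_radii(mol), `+`)

  with_seed(config$seed, {
    c1 <- config$c1; c2 <- config$c2
    if (config$c1c2 %in% c("start", "step")) {
      opt <- optimize_c1_c2(profile, mol)
      c1 <- opt$c1; c2 <- opt$c2
    }
    hyd_w <- if (c2 != 0) hydration_surface_weights(mol) else NULL
    Fm <- form_factor_matrix(mol, q, c1, c2, hyd_w)
    evalE <- function(xyz) {
      D <- as.matrix(stats::dist(xyz))
      ov <- rsum - D
      ov[!mask | ov <= 0] <- 0
      list(m = debye_sum(Fm, D, q), ev = config$ev_k * sum(ov^2))
    }
    xyz <- mol$xyz
    st <- evalE(xyz)
    gamma <- suppressWarnings(map_gamma(profile, st$m))
    chi2 <- chi_square(profile, st$m, gamma)
    sigma <- suppressMessages(map_sigma(chi2))
    weight <- if (bayesian) restraint_weight(M, sigma) else config$weight_mode

    com_mb <- function(xyz) colMeans(xyz[system$mobile, , drop = FALSE])
    nt <- length(tors)
    trace <- data.frame(step = seq_len(config$n_steps), chi2 = NA_real_,
                        score = NA_real_, gamma = NA_real_, sigma = NA_real_,
                        weight = NA_real_, acceptance = NA_real_,
                        ev = NA_real_)
    poses <- vector("list", config$n_steps)
    stall <- 0L; stalled <- FALSE

    for (step in seq_len(config$n_steps)) {
      acc <- 0L
      for (mv in seq_len(config$moves_per_step)) {
        type <- if (length(move_types) == 1) move_types else
          sample(move_types, 1)
        cand <- xyz
        if (type == "rigid") {
          ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
          ang <- stats::rnorm(1, 0, config$rot_step)
          shift <- stats::rnorm(3, 0, config$trans_step)
          mb <- system$mobile
          cand[mb, ] <- rotate_about_axis(cand[mb, , drop = FALSE],
                                          com_mb(cand), ax, ang)
          cand[mb, ] <- sweep(cand[mb, , drop = FALSE], 2, shift, `+`)
        } else {
          tq <- tors[[sample.int(nt, 1)]]
          sd <- if (tq$kind == "linker") config$dihedral_std_linker
                else config$dihedral_std_termini
          ang <- stats::rnorm(1, 0, sd)
          if (ang != 0 && length(tq$moving) > 0) {
            axis <- cand[tq$b, ] - cand[tq$a, ]
            cand[tq$moving, ] <- rotate_about_axis(
              cand[tq$moving, , drop = FALSE], cand[tq$a, ], axis, ang)
          }
        }
        stc <- evalE(cand)
        chi2c <- chi_square(profile, stc$m, gamma)
        dE <- weight * (chi2c - chi2) + (stc$ev - st$ev)
        if (metropolis_accept(dE, config$temperature)) {
          xyz <- cand; st <- stc; chi2 <- chi2c
          acc <- acc + 1L
        }
      }
      # nuisance update at maximum posterior
      gamma <- suppressWarnings(map_gamma(profile, st$m))
      chi2 <- chi_square(profile, st$m, gamma)
      if (bayesian) {
        sigma <- suppressMessages(map_sigma(chi2))
        weight <- restraint_weight(M, sigma)
      }
      if (config$c1c2 == "step") {
        cur <- mol; cur$xyz <- xyz
        opt <- optimize_c1_c2(profile, cur)
        c1 <- opt$c1; c2 <- opt$c2
        hyd_w <- if (c2 != 0) hydration_surface_weights(cur) else NULL
        Fm <- form_factor_matrix(mol, q, c1, c2, hyd_w)
        st <- evalE(xyz)
        gamma <- opt$gamma; chi2 <- opt$chi2
        if (bayesian) {
          sigma <- suppressMessages(map_sigma(chi2))
          weight <- restraint_weight(M, sigma)
        }
      }
      score <- weight * chi2 + M * log(if (bayesian) sigma else 1) + st$ev
      trace[step, 2:8] <- c(chi2, score, gamma, sigma, weight,
                            acc / config$moves_per_step, st$ev)
      fitq <- kabsch_fit(system$mobile_ref,
                         scale(xyz[system$mobile, , drop = FALSE],
                               scale = FALSE))
      poses[[step]] <- list(com = com_mb(xyz), quat = mat_to_quat(t(fitq$R)))
      stall <- if (acc == 0L) stall + 1L else 0L
      if (stall >= config$stall_window && !stalled) {
        warning("sampler stalled: no accepted moves for ",
                config$stall_window, " consecutive steps")
        stalled <- TRUE
      }
    }
    final <- mol; final$xyz <- xyz
    structure(list(trace = trace, final = final, poses = poses,
                   c1 = c1, c2 = c2, config = config,
                   move_types = move_types),
              class = "saxs_trajectory")
  })
}

#' @export
print.saxs_trajectory <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("MC trajectory (%s moves): %d steps, chi^2 %.4g -> %.4g, mean acceptance %.2f\n",
              paste(x$move_types, collapse = "+"), nrow(tr),
              tr$chi2[1], tr$chi2[nrow(tr)], mean(tr$acceptance)))
  invisible(x)
}

#' @export
plot.saxs_trajectory <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$step, tr$chi2, type = "l", log = "y",
                 xlab = "step", ylab = expression(chi^2), ...)
  graphics::plot(tr$step, tr$weight, type = "l", log = "y",
                 xlab = "step", ylab = "restraint weight")
  invisible(x)
}

#' Rigid-body docking driven by the SAXS restraint
#'
#' Each step performs `moves_per_step` Metropolis rotation/translation
#' proposals of the mobile body (energy = weighted chi-square at the
#' current nuisance parameters + excluded volume), then refreshes gamma and
#' sigma to their maximum posterior and, per `config$c1c2`, re-runs the
#' c1/c2 grid search.
#'
#' @param system a [rigid_system], mobile body placed (see
#'   [randomize_start()]).
#' @param profile experimental [saxs_profile].
#' @param config an [mc_config()].
#' @return a `saxs_trajectory`: per-step trace (chi2, score, gamma, sigma,
#'   weight, acceptance), per-step mobile pose (com + quaternion), the
#'   final structure and the c1/c2 used.
#' @export
rigid_dock <- function(system, profile, config = mc_config()) {
  run_mc(system, profile, config, "rigid")
}

#' Dihedral-space Monte Carlo refinement of flexible segments
#'
#' Each step is `moves_per_step` Metropolis moves, each a Gaussian
#' perturbation of one randomly chosen rotatable dihedral (scale 5e-2 rad
#' for termini, 5e-3 rad for linker segments by default), rebuilding the
#' downstream atoms by rigid rotation about the bond axis so covalent
#' geometry is unchanged by construction; gamma and sigma are refreshed
#' after each step (c1/c2 held fixed).
#'
#' @inheritParams rigid_dock
#' @export
dihedral_refine <- function(system, profile,
                            config = mc_config(moves_per_step = 10,
                                               c1c2 = "never")) {
  if (config$c1c2 == "step")
    config$c1c2 <- "start"  # refinement updates only gamma and sigma
  run_mc(system, profile, config, "dihedral")
}

#' Fixed-weight control simulation
#'
#' The identical sampler with energy `weight * chi^2 + excluded volume` and
#' no error-scale updates, for comparing hand-set restraint weights against
#' the automatic Bayesian weight.
#'
#' @inheritParams rigid_dock
#' @param weight fixed nonnegative restraint weight.
#' @param moves move types: `"rigid"`, `"dihedral"` or both.
#' @export
fixed_weight_run <- function(system, profile, weight,
                             config = mc_config(), moves = "rigid") {
  config$weight_mode <- as.numeric(weight)
  run_mc(system, profile, config, moves)
}
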