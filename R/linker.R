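# Construction of missing linker and terminal residues between fixed
# domains: a C-alpha path connecting the anchor atoms while avoiding the
# domains, staged minimization (steepest descent then conjugate gradient)
# under harmonic virtual-bond restraints, all-atom placement around the
# C-alpha trace, and sequential growth of termini with random phi/psi.
#
# Bonded geometry is enforced through harmonic distance restraints on 1-2
# (bond) and 1-3 (angle-equivalent) atom pairs with ideal values from
# standard residue geometry and uniform force constants; this reproduces
# the geometric content of a full bonded force field at the accuracy the
# coarse scattering model needs.

CA_CA_DIST <- 3.86  # trans peptide C-alpha virtual bond, Angstrom

#' Linker construction specification
#'
#' @param sequence one-letter residue sequence of the linker (may be empty).
#' @param start,end anchor C-alpha coordinates (numeric(3)) on the two
#'   domains the linker must join.
#' @param obstacle a [saxs_molecule]: the fixed domains the path must avoid.
#' @param D target consecutive C-alpha distance, Angstrom.
#' @return list of class `linker_spec`.
#' @export
linker_spec <- function(sequence, start, end, obstacle, D = CA_CA_DIST) {
  stopifnot(length(start) == 3, length(end) == 3, D > 0,
            inherits(obstacle, "saxs_molecule"))
  structure(list(sequence = toupper(sequence), start = as.numeric(start),
                 end = as.numeric(end), obstacle = obstacle, D = D),
            class = "linker_spec")
}

#' Minimization schedule
#'
#' Ordered phases of the staged minimizer.
#'
#' @param method character vector, `"sd"` (steepest descent) or `"cg"`
#'   (conjugate gradient) per phase.
#' @param steps positive step counts per phase.
#' @return data frame of class `minimization_schedule`.
#' @export
minimization_schedule <- function(method = c("sd", "cg"),
                                  steps = c(1000, 1000)) {
  stopifnot(length(method) == length(steps), all(steps > 0),
            all(method %in% c("sd", "cg")))
  structure(data.frame(method = method, steps = as.integer(steps)),
            class = c("minimization_schedule", "data.frame"))
}

# ---- generic distance-restraint energy ------------------------------------

# Energy/gradient of a network of pair restraints over free coordinates X
# (n x 3) with optional fixed obstacle points.  `pairs`: data frame i, j
# (free-atom indices), t (target), k, lower (TRUE = one-sided, penalize
# only d < t).  `fpairs`: i (free), j (row of `fixed`), same fields.
# `tether`: i, x, y, z, k harmonic position restraints.
restraint_energy <- function(X, pairs, fpairs = NULL, fixed = NULL,
                             tether = NULL, grad = FALSE) {
  E <- 0
  G <- if (grad) matrix(0, nrow(X), 3) else NULL
  pair_term <- function(dvec, tt, kk, lower) {
    d <- sqrt(rowSums(dvec^2))
    dev <- d - tt
    act <- if (any(lower)) !(lower & dev > 0) else rep(TRUE, length(d))
    dev[!act] <- 0
    list(E = sum(kk * dev^2),
         coef = ifelse(d > 1e-12, 2 * kk * dev / pmax(d, 1e-12), 0))
  }
  if (!is.null(pairs) && nrow(pairs) > 0) {
    dvec <- X[pairs$i, , drop = FALSE] - X[pairs$j, , drop = FALSE]
    pt <- pair_term(dvec, pairs$t, pairs$k, pairs$lower)
    E <- E + pt$E
    if (grad) {
      gv <- dvec * pt$coef
      for (c in 1:3) {
        G[, c] <- G[, c] + tapply_add(gv[, c], pairs$i, nrow(X)) -
          tapply_add(gv[, c], pairs$j, nrow(X))
      }
    }
  }
  if (!is.null(fpairs) && nrow(fpairs) > 0) {
    dvec <- X[fpairs$i, , drop = FALSE] - fixed[fpairs$j, , drop = FALSE]
    pt <- pair_term(dvec, fpairs$t, fpairs$k, fpairs$lower)
    E <- E + pt$E
    if (grad) {
      gv <- dvec * pt$coef
      for (c in 1:3)
        G[, c] <- G[, c] + tapply_add(gv[, c], fpairs$i, nrow(X))
    }
  }
  if (!is.null(tether) && nrow(tether) > 0) {
    dvec <- X[tether$i, , drop = FALSE] -
      as.matrix(tether[, c("x", "y", "z")])
    E <- E + sum(tether$k * rowSums(dvec^2))
    if (grad) {
      gv <- 2 * tether$k * dvec
      for (c in 1:3)
        G[, c] <- G[, c] + tapply_add(gv[, c], tether$i, nrow(X))
    }
  }
  if (grad) list(E = E, G = G) else E
}

tapply_add <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Staged minimizer: steepest descent with backtracking step control, then
# conjugate gradient via stats::optim.
minimize_energy <- function(X, efun, gfun, schedule) {
  n <- nrow(X)
  for (ph in seq_len(nrow(schedule))) {
    if (schedule$method[ph] == "sd") {
      lr <- 1e-3
      E <- efun(as.vector(X))
      for (s in seq_len(schedule$steps[ph])) {
        G <- matrix(gfun(as.vector(X)), n, 3)
        gn <- sqrt(sum(G^2))
        if (gn < 1e-10) break
        cand <- X - lr * G
        Ec <- efun(as.vector(cand))
        if (Ec <= E) { X <- cand; E <- Ec; lr <- lr * 1.2 }
        else lr <- lr / 2
      }
    } else {
      res <- stats::optim(as.vector(X), efun, gfun, method = "CG",
                          control = list(maxit = schedule$steps[ph]))
      X <- matrix(res$par, n, 3)
    }
  }
  X
}

# ---- C-alpha path ---------------------------------------------------------

#' Initial C-alpha path between two anchors avoiding the domains
#'
#' Places the linker C-alpha positions on the straight line between the
#' anchors, then iteratively pushes any position that falls inside an
#' obstacle atom's exclusion sphere outward along the repulsion direction.
#' The staged minimizer ([minimize_ca()]) does the real geometric work.
#'
#' @param spec a [linker_spec].
#' @param seed RNG seed (used to break ties when a point sits exactly on an
#'   obstacle center).
#' @param clearance exclusion radius around obstacle atoms, Angstrom
#'   (default `1.5 * D`, matching the minimizer's contact distance).
#' @param max_iter push iterations before a construction error.
#' @return matrix of `nchar(sequence)` C-alpha positions (0 rows for an
#'   empty sequence).
#' @export
build_ca_path <- function(spec, seed = 1, clearance = 1.5 * spec$D,
                          max_iter = 200) {
  n <- nchar(spec$sequence)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  obs <- spec$obstacle$xyz
  chord <- spec$end - spec$start
  cl <- sqrt(sum(chord^2))
  L <- (n + 1) * spec$D        # natural chain length at ideal spacing
  if (L <= cl * (1 + 1e-9)) {
    # chain is taut: straight line
    t <- seq_len(n) / (n + 1)
    P <- outer(t, chord) + rep(spec$start, each = n)
  } else {
    # slack chain: circular arc of length L over the chord, bowed away
    # from the obstacle centroid so the detour starts outside the domains
    th <- stats::uniroot(function(th) 2 * sin(th / 2) / th - cl / L,
                         c(1e-6, 2 * pi - 1e-6))$root
    R <- L / th
    u <- chord / cl
    away <- spec$start + chord / 2 - colMeans(obs)
    away <- away - sum(away * u) * u
    if (sqrt(sum(away^2)) < 1e-6) {          # chord points at the centroid
      away <- c(u[2], -u[1], 0)
      if (sqrt(sum(away^2)) < 1e-6) away <- c(0, u[3], -u[2])
    }
    v <- away / sqrt(sum(away^2))
    center <- spec$start + chord / 2 - v * R * cos(th / 2)
    a0 <- th / 2
    ang <- seq(-a0, a0, length.out = n + 2)[2:(n + 1)]
    P <- t(vapply(ang, function(a)
      center + R * cos(a) * v + R * sin(a) * u, numeric(3)))
  }
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      moved <- FALSE
      for (i in seq_len(n)) {
        d2 <- rowSums(sweep(obs, 2, P[i, ])^2)
        j <- which.min(d2)
        if (d2[j] < clearance^2) {
          dir <- P[i, ] - obs[j, ]
          nd <- sqrt(sum(dir^2))
          if (nd < 1e-9) { dir <- stats::rnorm(3); nd <- sqrt(sum(dir^2)) }
          P[i, ] <- obs[j, ] + dir / nd * (clearance * 1.05)
          moved <- TRUE
        }
      }
      if (!moved) return(P)
    }
  })
  # verify final clearance
  for (i in seq_len(n)) {
    if (min(rowSums(sweep(obs, 2, P[i, ])^2)) < clearance^2)
      stop("C-alpha path search exhausted: anchors may be buried")
  }
  P
}

# restraint network for the C-alpha chain (anchors fixed, linker free)
ca_network <- function(n, spec, k_bond = 10, k_ev = 10) {
  # virtual bonds along start - p1 - ... - pn - end
  pairs <- NULL
  if (n >= 2)
    pairs <- data.frame(i = 1:(n - 1), j = 2:n, t = spec$D, k = k_bond,
                        lower = FALSE)
  # linker self-avoidance: non-adjacent pairs, contact distance D
  if (n >= 3) {
    cmb <- utils::combn(n, 2)
    keep <- cmb[2, ] - cmb[1, ] > 1
    if (any(keep))
      pairs <- rbind(pairs, data.frame(i = cmb[1, keep], j = cmb[2, keep],
                                       t = spec$D, k = k_ev, lower = TRUE))
  }
  fixed <- rbind(spec$start, spec$end, spec$obstacle$xyz)
  fpairs <- data.frame(i = c(1, n), j = c(1, 2), t = spec$D, k = k_bond,
                       lower = FALSE)
  # linker (radius D/2) vs obstacle atoms (radius D): contact 1.5 D.
  # The anchor atoms themselves are bonded to the terminal linker residues
  # and carry no clash term; obstacle atoms in an anchor's covalent
  # neighbourhood (within D) keep only the plain C-alpha contact D so the
  # chain can actually attach.
  obs <- spec$obstacle$xyz
  d_anchor <- pmin(sqrt(rowSums(sweep(obs, 2, spec$start)^2)),
                   sqrt(rowSums(sweep(obs, 2, spec$end)^2)))
  far <- which(d_anchor > spec$D)
  near <- which(d_anchor > 1e-6 & d_anchor <= spec$D)
  add_obs <- function(js, t) {
    if (length(js) == 0) return(NULL)
    grid <- expand.grid(i = seq_len(n), j = 2 + js)
    data.frame(i = grid$i, j = grid$j, t = t, k = k_ev, lower = TRUE)
  }
  fpairs <- rbind(fpairs, add_obs(far, 1.5 * spec$D), add_obs(near, spec$D))
  list(pairs = pairs, fpairs = fpairs, fixed = fixed)
}

#' Minimize a C-alpha linker path
#'
#' Staged minimization (default 1,000 steepest-descent then 1,000
#' conjugate-gradient steps) of harmonic virtual-bond restraints (target
#' `D`) between consecutive C-alpha positions including the anchors, plus
#' one-sided excluded-volume restraints: linker C-alpha contact distance
#' `D` among themselves and `1.5 D` against obstacle atoms (whose effective
#' diameter `2 D` pushes the linker outside the domains).
#'
#' @param path matrix from [build_ca_path()].
#' @param spec the [linker_spec].
#' @param schedule a [minimization_schedule()].
#' @param k_bond,k_ev force constants (score units per square Angstrom).
#' @return list: `path` (minimized positions), `energy`, `converged`
#'   (consecutive distances within `D +/- 0.1` and no residual clash).
#' @export
minimize_ca <- function(path, spec, schedule = minimization_schedule(),
                        k_bond = 10, k_ev = 10) {
  n <- nrow(path)
  if (n == 0) return(list(path = path, energy = 0, converged = TRUE))
  net <- ca_network(n, spec, k_bond, k_ev)
  efun <- function(v) restraint_energy(matrix(v, n, 3), net$pairs,
                                       net$fpairs, net$fixed)
  gfun <- function(v) as.vector(restraint_energy(matrix(v, n, 3), net$pairs,
                                                 net$fpairs, net$fixed,
                                                 grad = TRUE)$G)
  P <- minimize_energy(path, efun, gfun, schedule)
  chain <- rbind(spec$start, P, spec$end)
  dists <- sqrt(rowSums(diff(chain)^2))
  clash <- efun(as.vector(P)) -
    restraint_energy(P, net$pairs[!net$pairs$lower, , drop = FALSE],
                     net$fpairs[!net$fpairs$lower, , drop = FALSE], net$fixed)
  list(path = P, energy = efun(as.vector(P)),
       converged = all(abs(dists - spec$D) <= 0.1) && clash < 0.01)
}

# ---- all-atom placement ---------------------------------------------------

# ideal bond lengths / 1-3 distances for backbone + CB construction
BOND_N_CA <- 1.458; BOND_CA_C <- 1.525; BOND_C_N <- 1.329
BOND_C_O <- 1.231; BOND_CA_CB <- 1.53

d13 <- function(b1, b2, theta) sqrt(b1^2 + b2^2 - 2 * b1 * b2 * cos(theta))

backbone_atoms <- function(resname, side_chains) {
  at <- c("N", "CA", "C", "O")
  if (side_chains && resname != "GLY") at <- c(at, "CB")
  at
}

#' Place backbone atoms around a minimized C-alpha path
#'
#' Backbone (N, CA, C, O; plus CB for non-glycine when `side_chains =
#' TRUE`) atoms are initialized uniformly at random in a sphere of diameter
#' `D` around each C-alpha, then minimized in two phases: (1) bonded terms
#' only (harmonic 1-2 and 1-3 distance restraints at ideal peptide
#' geometry, plus a C-alpha tether to the input path), 250 steepest-descent
#' + 1,000 conjugate-gradient steps; (2) the same plus one-sided
#' excluded-volume restraints with standard van der Waals radii against
#' self and the obstacle, 250 + 1,000 steps again.
#'
#' @param ca_path minimized C-alpha positions ([minimize_ca()]).
#' @param spec the [linker_spec].
#' @param seed RNG seed for the random initial placement.
#' @param side_chains also build C-beta atoms.
#' @param bond_tol relative bond-length tolerance of the acceptance check.
#' @return a [saxs_molecule] fragment (flexible, rigid group 0), or an
#'   error if clashes/bond deviations remain (caller retries with a new
#'   seed).
#' @export
place_all_atoms <- function(ca_path, spec, seed = 1, side_chains = FALSE,
                            bond_tol = 0.05) {
  n <- nrow(ca_path)
  if (n == 0) stop("empty C-alpha path")
  seq1 <- strsplit(spec$sequence, "")[[1]]
  res3 <- unname(AA_THREE[seq1])
  res3[is.na(res3)] <- "GLY"
  atoms <- NULL
  for (r in seq_len(n)) {
    at <- backbone_atoms(res3[r], side_chains)
    atoms <- rbind(atoms, data.frame(element = substr(at, 1, 1), resid = r,
                                     resname = res3[r], atom = at,
                                     chain = "L", stringsAsFactors = FALSE))
  }
  na <- nrow(atoms)
  X <- with_seed(seed, {
    u <- matrix(stats::rnorm(3 * na), na, 3)
    u <- u / sqrt(rowSums(u^2)) * (spec$D / 2) * stats::runif(na)^(1 / 3)
    ca_path[atoms$resid, , drop = FALSE] + u
  })
  ca_idx <- which(atoms$atom == "CA")
  X[ca_idx, ] <- ca_path  # start CA exactly on the path

  # bonded network: 1-2 bonds and 1-3 (angle-equivalent) distances
  idx_of <- function(r, a) which(atoms$resid == r & atoms$atom == a)
  kb <- 100
  P <- list()
  add <- function(i, j, t) {
    if (length(i) == 1 && length(j) == 1)
      P[[length(P) + 1]] <<- data.frame(i = i, j = j, t = t, k = kb,
                                        lower = FALSE)
  }
  deg <- pi / 180
  for (r in seq_len(n)) {
    Ni <- idx_of(r, "N"); CAi <- idx_of(r, "CA"); Ci <- idx_of(r, "C")
    Oi <- idx_of(r, "O"); CBi <- idx_of(r, "CB")
    add(Ni, CAi, BOND_N_CA); add(CAi, Ci, BOND_CA_C); add(Ci, Oi, BOND_C_O)
    add(Ni, Ci, d13(BOND_N_CA, BOND_CA_C, 111 * deg))
    add(CAi, Oi, d13(BOND_CA_C, BOND_C_O, 120.8 * deg))
    if (length(CBi) == 1) {
      add(CAi, CBi, BOND_CA_CB)
      add(Ni, CBi, d13(BOND_N_CA, BOND_CA_CB, 110.5 * deg))
      add(Ci, CBi, d13(BOND_CA_C, BOND_CA_CB, 110.1 * deg))
    }
    if (r < n) {
      Nn <- idx_of(r + 1, "N"); CAn <- idx_of(r + 1, "CA")
      add(Ci, Nn, BOND_C_N)
      add(CAi, Nn, d13(BOND_CA_C, BOND_C_N, 116.2 * deg))
      add(Oi, Nn, d13(BOND_C_O, BOND_C_N, 123 * deg))
      add(Ci, CAn, d13(BOND_C_N, BOND_N_CA, 121.7 * deg))
    }
  }
  bonded <- do.call(rbind, P)
  tether <- data.frame(i = ca_idx, x = ca_path[, 1], y = ca_path[, 2],
                       z = ca_path[, 3], k = 10)
  # clash network (phase 2): self pairs |delta resid| > 1, plus obstacle
  rads <- VDW_RADII[atoms$element]; rads[is.na(rads)] <- 1.7
  cmb <- utils::combn(na, 2)
  keep <- abs(atoms$resid[cmb[1, ]] - atoms$resid[cmb[2, ]]) > 1
  clash_self <- if (any(keep))
    data.frame(i = cmb[1, keep], j = cmb[2, keep],
               t = rads[cmb[1, keep]] + rads[cmb[2, keep]], k = 10,
               lower = TRUE) else NULL
  obs <- spec$obstacle$xyz
  orad <- atom_radii(spec$obstacle)
  grid <- expand.grid(i = seq_len(na), j = seq_len(nrow(obs)))
  clash_obs <- data.frame(i = grid$i, j = grid$j,
                          t = rads[grid$i] + orad[grid$j], k = 10,
                          lower = TRUE)

  run <- function(X, pairs, fpairs, fixed, sched) {
    efun <- function(v) restraint_energy(matrix(v, na, 3), pairs, fpairs,
                                         fixed, tether)
    gfun <- function(v) as.vector(restraint_energy(matrix(v, na, 3), pairs,
                                                   fpairs, fixed, tether,
                                                   grad = TRUE)$G)
    minimize_energy(X, efun, gfun, sched)
  }
  X <- run(X, bonded, NULL, NULL, minimization_schedule(steps = c(250, 1000)))
  X <- run(X, rbind(bonded, clash_self), clash_obs, obs,
           minimization_schedule(steps = c(250, 1000)))

  # acceptance checks
  dvec <- X[bonded$i, , drop = FALSE] - X[bonded$j, , drop = FALSE]
  reldev <- abs(sqrt(rowSums(dvec^2)) - bonded$t) / bonded$t
  clash_pen <- restraint_energy(X, clash_self, clash_obs, obs)
  if (max(reldev) > bond_tol || clash_pen > 0.01)
    stop("all-atom placement rejected (bond deviation ",
         signif(max(reldev), 3), ", clash ", signif(clash_pen, 3),
         "); retry with a new seed")
  saxs_molecule(atoms, X, rigid_group = rep(0L, na))
}

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# ---- termini growth -------------------------------------------------------

#' Grow terminal residues with random backbone dihedrals
#'
#' Residues are added one at a time beyond the existing chain ends with
#' random phi/psi (planar trans peptide), resampling the dihedrals of a
#' residue until it causes no clash.  Bead (C-alpha only) molecules grow
#' single beads per residue at the virtual-bond distance with random
#' placement angles.
#'
#' @param mol a [saxs_molecule].
#' @param n_term_seq,c_term_seq one-letter sequences to prepend/append
#'   (empty string = no growth at that end).
#' @param seed RNG seed.
#' @param max_resample per-residue clash-resampling budget.
#' @return the extended [saxs_molecule]; new atoms are flexible (group 0).
#' @export
attach_termini <- function(mol, n_term_seq = "", c_term_seq = "", seed = 1,
                           max_resample = 1000) {
  if (nchar(n_term_seq) == 0 && nchar(c_term_seq) == 0) return(mol)
  with_seed(seed, {
    if (nchar(c_term_seq) > 0)
      for (aa in strsplit(c_term_seq, "")[[1]])
        mol <- grow_residue(mol, aa, end = "C", max_resample)
    if (nchar(n_term_seq) > 0)
      for (aa in rev(strsplit(n_term_seq, "")[[1]]))
        mol <- grow_residue(mol, aa, end = "N", max_resample)
  })
  mol
}

# clash test of candidate atom positions against the existing molecule
grow_clash <- function(mol, new_xyz, new_resid) {
  r_new <- 1.7
  rads <- atom_radii(mol)
  ok_res <- abs(mol$atoms$resid - new_resid) > 1
  if (!any(ok_res)) return(FALSE)
  D <- sqrt(pmax(outer(rowSums(new_xyz^2),
                       rowSums(mol$xyz[ok_res, , drop = FALSE]^2), `+`) -
                   2 * new_xyz %*% t(mol$xyz[ok_res, , drop = FALSE]), 0))
  any(sweep(D, 2, rads[ok_res] + r_new) < 0)
}

grow_residue <- function(mol, aa, end, max_resample) {
  bead <- mol$bead
  res <- mol$atoms$resid
  if (end == "C") { r0 <- max(res); rn <- r0 + 1L } else {
    r0 <- min(res); rn <- r0 - 1L
  }
  for (try in seq_len(max_resample)) {
    if (bead) {
      idx <- order(res)
      chain <- mol$xyz[idx, , drop = FALSE]
      if (end == "N") chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
      m <- nrow(chain)
      pos <- if (m >= 3) {
        place_atom_internal(chain[m - 2, ], chain[m - 1, ], chain[m, ],
                            CA_CA_DIST, stats::runif(1, 1.2, 2.4),
                            stats::runif(1, -pi, pi))
      } else {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        chain[m, ] + CA_CA_DIST * u
      }
      new_xyz <- matrix(pos, 1, 3)
      new_atoms <- mol$atoms[1, , drop = FALSE]
      new_atoms$resid <- rn; new_atoms$atom <- "CA"
      new_atoms$resname <- "BEA"
    } else {
      anchor <- res == r0
      nm <- mol$atoms$atom
      gx <- function(a) mol$xyz[which(anchor & nm == a)[1], ]
      phi <- stats::runif(1, -pi, pi); psi <- stats::runif(1, -pi, pi)
      deg <- pi / 180
      if (end == "C") {
        Np <- place_atom_internal(gx("N"), gx("CA"), gx("C"),
                                  BOND_C_N, 116.2 * deg, psi)
        CAp <- place_atom_internal(gx("CA"), gx("C"), Np,
                                   BOND_N_CA, 121.7 * deg, pi)
        Cp <- place_atom_internal(gx("C"), Np, CAp,
                                  BOND_CA_C, 111 * deg, phi)
        Op <- place_atom_internal(Np, CAp, Cp, BOND_C_O, 120.8 * deg, pi)
        pos <- rbind(Np, CAp, Cp, Op)
      } else {
        Cp <- place_atom_internal(gx("C"), gx("CA"), gx("N"),
                                  BOND_C_N, 121.7 * deg, phi)
        CAp <- place_atom_internal(gx("CA"), gx("N"), Cp,
                                   BOND_CA_C, 116.2 * deg, pi)
        Np <- place_atom_internal(gx("N"), Cp, CAp,
                                  BOND_N_CA, 111 * deg, psi)
        Op <- place_atom_internal(CAp, gx("N"), Cp, BOND_C_O, 120.8 * deg, pi)
        pos <- rbind(Np, CAp, Cp, Op)
      }
      new_xyz <- pos
      rn3 <- AA_THREE[toupper(aa)]; if (is.na(rn3)) rn3 <- "GLY"
      new_atoms <- data.frame(element = c("N", "C", "C", "O"), resid = rn,
                              resname = rn3, atom = c("N", "CA", "C", "O"),
                              chain = mol$atoms$chain[which(res == r0)[1]],
                              stringsAsFactors = FALSE)
      miss <- setdiff(names(mol$atoms), names(new_atoms))
      for (mcol in miss) new_atoms[[mcol]] <- mol$atoms[[mcol]][1]
    }
    if (!grow_clash(mol, new_xyz, rn)) {
      out_atoms <- rbind(mol$atoms, new_atoms)
      out_xyz <- rbind(mol$xyz, new_xyz)
      return(saxs_molecule(out_atoms, out_xyz,
                           rigid_group = c(mol$rigid_group,
                                           rep(0L, nrow(new_xyz))),
                           bead = bead))
    }
  }
  stop("terminus growth failed: residue ", rn, " clashed for ",
       max_resample, " resamples")
}

#' Add a bead linker between the two bodies of a pose
#'
#' Convenience driver for coarse-grained poses: builds and minimizes a
#' C-alpha path between the nearest-to-gap residues of the two rigid
#' bodies, inserts the linker beads as flexible residues, and renumbers
#' residues to keep the chain consecutive.
#'
#' @param mol a bead-mode [saxs_molecule] with rigid groups 1 and 2.
#' @param n_res number of linker beads.
#' @param seed RNG seed for path construction.
#' @param D virtual-bond target distance.
#' @return a [saxs_molecule] with the linker inserted (flexible, group 0).
#' @export
add_bead_linker <- function(mol, n_res, seed = 1, D = CA_CA_DIST) {
  stopifnot(mol$bead, n_res >= 1)
  i1 <- which(mol$rigid_group == 1L)
  i2 <- which(mol$rigid_group == 2L)
  # anchors: the surface bead of each body facing the other body, so the
  # linker attaches at the inter-domain gap; residue numbering is swapped
  # so the anchors are the chain-terminal residues of their bodies
  com2 <- mol_com(mol, i2); com1 <- mol_com(mol, i1)
  a1 <- i1[which.min(rowSums(sweep(mol$xyz[i1, , drop = FALSE], 2, com2)^2))]
  a2 <- i2[which.min(rowSums(sweep(mol$xyz[i2, , drop = FALSE], 2, com1)^2))]
  swap <- function(r, i, j) { tmp <- r[i]; r[i] <- r[j]; r[j] <- tmp; r }
  res <- mol$atoms$resid
  res <- swap(res, a1, i1[which.max(res[i1])])
  res <- swap(res, a2, i2[which.min(res[i2])])
  mol$atoms$resid <- res
  spec <- linker_spec(strrep("G", n_res), mol$xyz[a1, ], mol$xyz[a2, ],
                      obstacle = mol, D = D)
  P <- build_ca_path(spec, seed = seed, clearance = D)
  # random jitter before minimization so different seeds explore
  # different linker conformations
  P <- with_seed(seed, P + matrix(stats::rnorm(length(P), 0, 0.5 * D),
                                  nrow(P), 3))
  fit <- minimize_ca(P, spec, k_bond = 10, k_ev = 10)
  la <- mol$atoms[rep(a1, n_res), , drop = FALSE]
  la$resid <- max(mol$atoms$resid[i1]) + seq_len(n_res)
  la$atom <- "CA"; la$resname <- "BEA"
  atoms <- rbind(mol$atoms[i1, , drop = FALSE], la,
                 mol$atoms[i2, , drop = FALSE])
  shift <- n_res
  atoms$resid <- c(mol$atoms$resid[i1], la$resid,
                   mol$atoms$resid[i2] + shift)
  xyz <- rbind(mol$xyz[i1, , drop = FALSE], fit$path,
               mol$xyz[i2, , drop = FALSE])
  saxs_molecule(atoms, xyz,
                rigid_group = c(rep(1L, length(i1)), rep(0L, n_res),
                                rep(2L, length(i2))), bead = TRUE)
}
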