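# Composite structure-determination driver: rigid-body docking replicas
# -> SOM clustering of poses -> per-neuron best-fit extraction -> linker
# construction -> dihedral Monte Carlo refinement, with a composite
# chi-square / restraint-weight trace across stage boundaries.

#' Workflow configuration
#'
#' Defaults follow the full-scale protocol (64 docking replicas of 500
#' steps, a 50 x 50 SOM, 2,000 refinement steps); `scale` shrinks every
#' stage proportionally for desk-sized runs.
#'
#' @param replicas independent docking replicas.
#' @param dock [mc_config()] of the docking stage.
#' @param som_shape SOM grid shape.
#' @param som an [som_config()].
#' @param keep_last fraction of each docking trajectory (from the end)
#'   whose poses train the SOM.
#' @param top_poses clash-free per-neuron poses carried into linker
#'   construction (ranked by chi-square).
#' @param linker_res linker length in residues/beads.
#' @param linkers_per_pose linker constructions tried per pose (lowest
#'   chi-square kept).
#' @param refine [mc_config()] of the dihedral refinement stage.
#' @param refine_top refined structures (best linked poses).
#' @param seed master seed; all stage seeds derive from it.
#' @param scale global scale factor applied to replicas, steps and map
#'   side (1 = full protocol).
#' @return list of class `workflow_config`.
#' @export
workflow_config <- function(replicas = 64,
                            dock = mc_config(n_steps = 500,
                                             moves_per_step = 100,
                                             c1c2 = "start"),
                            som_shape = c(50, 50),
                            som = som_config(),
                            keep_last = 0.4,
                            top_poses = 10,
                            linker_res = 6,
                            linkers_per_pose = 5,
                            refine = mc_config(n_steps = 2000,
                                               moves_per_step = 10,
                                               c1c2 = "never"),
                            refine_top = 3,
                            seed = 1, scale = 1) {
  if (scale != 1) {
    replicas <- max(2L, ceiling(replicas * scale))
    dock$n_steps <- max(20L, ceiling(dock$n_steps * scale))
    refine$n_steps <- max(20L, ceiling(refine$n_steps * scale))
    som_shape <- pmax(6L, ceiling(som_shape * sqrt(scale)))
    top_poses <- max(2L, ceiling(top_poses * scale))
  }
  structure(list(replicas = as.integer(replicas), dock = dock,
                 som_shape = som_shape, som = som, keep_last = keep_last,
                 top_poses = as.integer(top_poses),
                 linker_res = as.integer(linker_res),
                 linkers_per_pose = as.integer(linkers_per_pose),
                 refine = refine, refine_top = as.integer(refine_top),
                 seed = as.integer(seed), scale = scale),
            class = "workflow_config")
}

# chi2/gamma/sigma of a molecule against the profile at fixed c1/c2
score_structure <- function(mol, profile, c1, c2) {
  m <- compute_profile(mol, profile$q, c1 = c1, c2 = c2)$intensity
  g <- suppressWarnings(map_gamma(profile, m))
  x2 <- chi_square(profile, m, g)
  list(chi2 = x2, gamma = g, sigma = suppressMessages(map_sigma(x2)))
}

#' Run the staged docking -> SOM -> linker -> refinement workflow
#'
#' @param profile experimental [saxs_profile].
#' @param system a [rigid_system] of the two domains (no linker; the
#'   workflow builds it).
#' @param config a [workflow_config()].
#' @param out_dir optional directory: per-stage CSV traces, the composite
#'   trace and final PDB are written there.
#' @return object of class `saxs_workflow`: composite `trace` (stage,
#'   step, chi2, gamma, sigma, weight, acceptance), the trained `som`,
#'   selected `poses`, per-stage bests and the final refined structure
#'   with its fit.
#' @export
run_workflow <- function(profile, system, config = workflow_config(),
                         out_dir = NULL) {
  stopifnot(inherits(profile, "saxs_profile"), inherits(system, "rigid_system"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- config$seed

  ## stage 1: docking replicas -------------------------------------------
  descriptors <- NULL; chi2s <- NULL
  dock_traces <- vector("list", config$replicas)
  c1 <- 1; c2 <- 0
  for (r in seq_len(config$replicas)) {
    sys_r <- randomize_start(system, seed = seed + r)
    cfg <- config$dock
    cfg$seed <- seed + 7919L * r
    if (r > 1 && cfg$c1c2 == "start") {  # share stage-level c1/c2
      cfg$c1c2 <- "never"; cfg$c1 <- c1; cfg$c2 <- c2
    }
    traj <- rigid_dock(sys_r, profile, cfg)
    if (r == 1) { c1 <- traj$c1; c2 <- traj$c2 }
    dock_traces[[r]] <- traj$trace
    keep <- seq(from = ceiling(nrow(traj$trace) * (1 - config$keep_last)) + 1,
                to = nrow(traj$trace))
    keep <- keep[keep >= 1]
    descriptors <- rbind(descriptors,
                         t(vapply(traj$poses[keep],
                                  function(p) c(p$com, p$quat), numeric(7))))
    chi2s <- c(chi2s, traj$trace$chi2[keep])
  }
  best_dock_chi2 <- min(vapply(dock_traces, function(t) min(t$chi2),
                               numeric(1)))

  ## stage 2: SOM clustering of poses ------------------------------------
  som_cfg <- config$som
  som_cfg$seed <- seed + 101L
  som <- train_som(descriptors, shape = config$som_shape, config = som_cfg)
  bmu <- som_assign(som, descriptors)
  sel <- list()
  for (nrn in which(som$hits > 0)) {
    members <- which(bmu == nrn)
    bi <- members[which.min(chi2s[members])]
    rec <- reconstruct_pose(descriptors[bi, ], system)
    if (!rec$clash)
      sel[[length(sel) + 1]] <- list(neuron = nrn, mol = rec$mol,
                                     chi2 = chi2s[bi])
  }
  if (length(sel) == 0) stop("workflow: no clash-free pose could be extracted")
  ord <- order(vapply(sel, `[[`, numeric(1), "chi2"))
  sel <- sel[ord[seq_len(min(config$top_poses, length(sel)))]]

  ## stage 3: linker construction ----------------------------------------
  linked <- lapply(seq_along(sel), function(i) {
    pose <- sel[[i]]
    best <- NULL
    for (m in seq_len(config$linkers_per_pose)) {
      mol_l <- tryCatch(
        add_bead_linker(pose$mol, config$linker_res,
                        seed = seed + 331L * i + m),
        error = function(e) NULL)
      if (is.null(mol_l)) next
      sc <- score_structure(mol_l, profile, c1, c2)
      if (is.null(best) || sc$chi2 < best$chi2)
        best <- c(list(mol = mol_l), sc)
    }
    best
  })
  linked <- Filter(Negate(is.null), linked)
  if (length(linked) == 0) stop("workflow: linker construction failed everywhere")
  lord <- order(vapply(linked, `[[`, numeric(1), "chi2"))
  linked <- linked[lord]
  M <- nrow(profile)
  linker_trace <- data.frame(
    step = seq_along(linked),
    chi2 = vapply(linked, `[[`, numeric(1), "chi2"),
    score = NA_real_,
    gamma = vapply(linked, `[[`, numeric(1), "gamma"),
    sigma = vapply(linked, `[[`, numeric(1), "sigma"),
    weight = M / (2 * vapply(linked, `[[`, numeric(1), "sigma")^2),
    acceptance = NA_real_, ev = 0)

  ## stage 4: dihedral refinement ----------------------------------------
  refined <- list()
  refine_traces <- list()
  for (i in seq_len(min(config$refine_top, length(linked)))) {
    mol_l <- linked[[i]]$mol
    sys_l <- rigid_system(mol_l)
    cfg <- config$refine
    cfg$seed <- seed + 557L * i
    cfg$c1 <- c1; cfg$c2 <- c2
    traj <- dihedral_refine(sys_l, profile, cfg)
    refine_traces[[i]] <- traj$trace
    refined[[i]] <- list(mol = traj$final,
                         chi2 = traj$trace$chi2[nrow(traj$trace)])
  }
  bi <- which.min(vapply(refined, `[[`, numeric(1), "chi2"))
  final <- refined[[bi]]

  ## composite trace -------------------------------------------------------
  comp <- rbind(
    do.call(rbind, lapply(seq_along(dock_traces), function(r)
      cbind(stage = "dock", replica = r, dock_traces[[r]]))),
    cbind(stage = "link", replica = NA, linker_trace),
    do.call(rbind, lapply(seq_along(refine_traces), function(r)
      cbind(stage = "refine", replica = r, refine_traces[[r]]))))

  out <- structure(list(trace = comp, som = som, poses = sel,
                        linked = linked, final = final,
                        best_dock_chi2 = best_dock_chi2,
                        c1 = c1, c2 = c2, config = config),
                   class = "saxs_workflow")
  if (!is.null(out_dir)) {
    utils::write.csv(comp, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    write_pdb(final$mol, file.path(out_dir, "final.pdb"))
  }
  out
}

#' @export
print.saxs_workflow <- function(x, ...) {
  cat("Staged SAXS structure determination\n")
  cat(sprintf("  docking:    %d replicas, best chi^2 = %.4g\n",
              x$config$replicas, x$best_dock_chi2))
  cat(sprintf("  SOM:        %d x %d, %d poses extracted\n",
              x$config$som_shape[1], x$config$som_shape[2], length(x$poses)))
  cat(sprintf("  linker:     best linked chi^2 = %.4g\n", x$linked[[1]]$chi2))
  cat(sprintf("  refinement: final chi^2 = %.4g (c1 = %.3f, c2 = %.2f)\n",
              x$final$chi2, x$c1, x$c2))
  invisible(x)
}
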