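test_that("the excluded-volume penalty matches plug-in values and a pair oracle", {
  two <- function(d) saxs_molecule(
    data.frame(element = "C", resid = c(1, 5), resname = "GLY", atom = "CA",
               chain = "A", f0 = 1, volume = 0, radius = 2),
    rbind(c(0, 0, 0), c(d, 0, 0)), rigid_group = c(1L, 2L), bead = TRUE)
  expect_equal(excluded_volume(two(4.5)), 0)
  expect_equal(excluded_volume(two(3), k = 1), 1)      # (2 + 2 - 3)^2
  expect_equal(excluded_volume(two(3), k = 2.5), 2.5)

  # brute-force oracle on a random system with mixed group membership
  set.seed(9)
  n <- 200
  mol <- saxs_molecule(
    data.frame(element = "C", resid = seq(1, 3 * n, by = 3), resname = "BEA",
               atom = "CA", chain = "A", f0 = 1, volume = 0,
               radius = runif(n, 1, 2.5)),
    matrix(runif(3 * n, 0, 25), n, 3),
    rigid_group = sample(0:2, n, replace = TRUE), bead = TRUE)
  r <- mol$atoms$radius; g <- mol$rigid_group
  acc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (g[i] == g[j] && g[i] > 0) next
    if (abs(mol$atoms$resid[i] - mol$atoms$resid[j]) <= 1) next
    d <- sqrt(sum((mol$xyz[i, ] - mol$xyz[j, ])^2))
    ov <- r[i] + r[j] - d
    if (ov > 0) acc <- acc + ov^2
  }
  expect_equal(excluded_volume(mol), acc, tolerance = 1e-12)
})

test_that("Metropolis acceptance satisfies detailed balance statistics", {
  # downhill and zero-cost moves always accept
  expect_true(all(vapply(1:100, function(i)
    saxsbayes:::metropolis_accept(-runif(1)), logical(1))))
  expect_true(saxsbayes:::metropolis_accept(0))
  # uphill acceptance matches exp(-dE) within binomial error
  set.seed(4)
  dE <- 1.2
  n <- 1e4
  acc <- mean(vapply(seq_len(n), function(i)
    saxsbayes:::metropolis_accept(dE), logical(1)))
  p <- exp(-dE)
  expect_lt(abs(acc - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("random starting poses are clash-free, distinct and isotropic", {
  tc <- toy_conditions(seed = 5)
  sys <- rigid_system(tc$mol)
  s1 <- randomize_start(sys, seed = 1)
  s2 <- randomize_start(sys, seed = 2)
  expect_equal(excluded_volume(s1$mol), 0)
  expect_equal(excluded_volume(s2$mol), 0)
  expect_gt(max(abs(s1$mol$xyz - s2$mol$xyz)), 1)
  # orientation uniformity: E|<q, ref>| = 4 / (3 pi) on the unit 4-sphere
  set.seed(11)
  dots <- replicate(4000, abs(quat_random()[1]))
  expect_lt(abs(mean(dots) - 4 / (3 * pi)), 0.02)
})

test_that("docking keeps rigid bodies exactly rigid and is seed-reproducible", {
  tc <- toy_conditions(seed = 5)
  sys <- randomize_start(rigid_system(tc$mol), seed = 3)
  cfg <- mc_config(n_steps = 15, moves_per_step = 10, seed = 8,
                   c1c2 = "never")
  tr1 <- rigid_dock(sys, tc$prof, cfg)
  tr2 <- rigid_dock(sys, tc$prof, cfg)
  expect_identical(tr1$trace, tr2$trace)
  expect_identical(tr1$final$xyz, tr2$final$xyz)
  for (grp in 1:2) {
    idx <- which(tc$mol$rigid_group == grp)
    d0 <- dist(sys$mol$xyz[idx, ])
    d1 <- dist(tr1$final$xyz[idx, ])
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
  expect_equal(nrow(tr1$trace), 15)
  expect_true(all(tr1$trace$acceptance >= 0 & tr1$trace$acceptance <= 1))
  # Bayesian weight column is M / 2 sigma^2 throughout
  expect_equal(tr1$trace$weight,
               nrow(tc$prof) / (2 * tr1$trace$sigma^2))
})

test_that("dihedral moves change torsions only: covalent geometry is exact", {
  tc <- toy_conditions(seed = 7, linker = 5)
  sys <- rigid_system(tc$mol)
  expect_gt(length(sys$torsions), 0)
  cfg <- mc_config(n_steps = 12, moves_per_step = 10, seed = 2,
                   c1c2 = "never", dihedral_std_linker = 0.3,
                   dihedral_std_termini = 0.3)
  tr <- dihedral_refine(sys, tc$prof, cfg)
  expect_gt(sum(tr$trace$acceptance), 0)
  # virtual bond lengths along the chain unchanged
  expect_lt(max(abs(bead_chain_spacing(tr$final) -
                      bead_chain_spacing(tc$mol))), 1e-9)
  # rigid bodies still internally rigid
  for (grp in 1:2) {
    idx <- which(tc$mol$rigid_group == grp)
    expect_lt(max(abs(dist(tr$final$xyz[idx, ]) -
                        dist(tc$mol$xyz[idx, ]))), 1e-9)
  }
  # zero-amplitude perturbations give the identity trajectory
  cfg0 <- mc_config(n_steps = 3, moves_per_step = 5, seed = 2,
                    c1c2 = "never", dihedral_std_linker = 0,
                    dihedral_std_termini = 0)
  tr0 <- dihedral_refine(sys, tc$prof, cfg0)
  expect_equal(tr0$final$xyz, tc$mol$xyz)
  # refinement without flexible atoms is a configuration error
  expect_error(dihedral_refine(rigid_system(toy_conditions(seed = 5)$mol),
                               tc$prof, cfg),
               "no flexible")
})

test_that("fixed-weight sampling ignores sigma and weight zero ignores the data", {
  tc <- toy_conditions(seed = 5)
  sys <- randomize_start(rigid_system(tc$mol), seed = 3)
  cfg <- mc_config(n_steps = 10, moves_per_step = 10, seed = 6,
                   c1c2 = "never")
  tr <- fixed_weight_run(sys, tc$prof, weight = 2.5, cfg)
  expect_true(all(tr$trace$weight == 2.5))
  tr0 <- fixed_weight_run(sys, tc$prof, weight = 0, cfg)
  expect_true(all(tr0$trace$weight == 0))
  # with weight zero only the clash term acts: every clash-free rigid
  # move is accepted
  expect_true(all(tr0$trace$acceptance >= 0.9))
})

test_that("a stalled sampler is reported but keeps running", {
  # noise-free data evaluated at the generating pose: chi^2 sits at an
  # exact minimum, so under a huge fixed weight every proposal is uphill
  tc <- toy_conditions(seed = 5)
  prof0 <- simulate_profile(tc$mol, tc$q, noise = noise_spec(seed = 1),
                            perturb = FALSE)
  sys <- rigid_system(tc$mol)
  cfg <- mc_config(n_steps = 12, moves_per_step = 5, seed = 1,
                   c1c2 = "never", stall_window = 10)
  expect_warning(tr <- fixed_weight_run(sys, prof0, weight = 1e12, cfg),
                 "stalled")
  expect_equal(nrow(tr$trace), 12)
  expect_true(all(tr$trace$acceptance == 0))
})
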