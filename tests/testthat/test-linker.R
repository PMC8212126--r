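far_obstacle <- function() saxs_molecule(
  data.frame(element = "C", resid = 1, resname = "GLY", atom = "CA",
             chain = "B"), matrix(c(500, 500, 500), 1), 1L)

test_that("an obstacle-free taut chain is laid out on the straight line", {
  D <- 3.86
  spec <- linker_spec("GGGG", c(0, 0, 0), c(5 * D, 0, 0), far_obstacle())
  P <- build_ca_path(spec, seed = 1)
  expect_equal(nrow(P), 4)
  # collinear with the anchors
  expect_lt(max(abs(P[, 2:3])), 1e-9)
  chain <- rbind(spec$start, P, spec$end)
  d <- sqrt(rowSums(diff(chain)^2))
  expect_true(all(d <= D * 1.01))
  # degenerate empty sequence: validates anchors, returns nothing
  spec0 <- linker_spec("", c(0, 0, 0), c(5, 0, 0), far_obstacle())
  expect_equal(nrow(build_ca_path(spec0, 1)), 0)
})

test_that("the path detours around an obstacle sitting on the direct line", {
  D <- 3.86
  obst <- saxs_molecule(
    data.frame(element = "C", resid = 1, resname = "GLY", atom = "CA",
               chain = "B", f0 = 1, volume = 0, radius = 3),
    matrix(c(10, 0, 0), 1), 1L, bead = TRUE)
  spec <- linker_spec("GGGGG", c(0, 0, 0), c(20, 0, 0), obst)
  P <- build_ca_path(spec, seed = 2, clearance = 5)
  dmin <- min(sqrt(rowSums(sweep(P, 2, c(10, 0, 0))^2)))
  expect_gt(dmin, 5)
})

test_that("the staged minimizer restores ideal spacing and never raises the energy", {
  D <- 3.86
  spec <- linker_spec(strrep("G", 6), c(0, 0, 0), c(7 * D, 0, 0),
                      far_obstacle())
  # already-ideal straight chain with no obstacle: a fixed point
  ideal <- outer(seq_len(6) * D, c(1, 0, 0))
  out <- minimize_ca(ideal, spec)
  expect_lt(out$energy, 1e-10)
  expect_lt(max(abs(out$path - ideal)), 1e-6)
  expect_true(out$converged)

  # stretched initial chain (5 A spacing, slightly off-axis so descent
  # can buckle it) relaxes to D +/- 0.1 between anchors 7 D apart
  spec2 <- linker_spec(strrep("G", 6), c(0, 0, 0), c(7 * D, 0, 0),
                       far_obstacle())
  set.seed(2)
  stretched <- outer(seq_len(6) * 5, c(1, 0, 0)) +
    matrix(rnorm(18, 0, 0.1), 6, 3)
  net <- saxsbayes:::ca_network(6, spec2)
  e0 <- saxsbayes:::restraint_energy(stretched, net$pairs, net$fpairs,
                                     net$fixed)
  out2 <- minimize_ca(stretched, spec2)
  expect_lte(out2$energy, e0)
  chain <- rbind(spec2$start, out2$path, spec2$end)
  d <- sqrt(rowSums(diff(chain)^2))
  expect_lt(max(abs(d - D)), 0.1)
  expect_true(out2$converged)
})

test_that("all-atom placement yields ideal covalent geometry without clashes", {
  D <- 3.86
  spec <- linker_spec("GAGSG", c(0, 0, 0), c(6 * D, 0, 0), far_obstacle())
  P <- build_ca_path(spec, seed = 1)
  P <- minimize_ca(P, spec)$path
  for (s in 1:3) {
    frag <- place_all_atoms(P, spec, seed = s)
    nca <- which(frag$atoms$atom == "N")
    # N-CA bonds within the 5% band around 1.458 A
    for (r in unique(frag$atoms$resid)) {
      i <- which(frag$atoms$resid == r & frag$atoms$atom == "N")
      j <- which(frag$atoms$resid == r & frag$atoms$atom == "CA")
      d <- sqrt(sum((frag$xyz[i, ] - frag$xyz[j, ])^2))
      expect_gt(d, 1.39); expect_lt(d, 1.53)
    }
    # peptide connectivity: C(r) - N(r+1) bonded
    for (r in 1:4) {
      i <- which(frag$atoms$resid == r & frag$atoms$atom == "C")
      j <- which(frag$atoms$resid == r + 1 & frag$atoms$atom == "N")
      expect_lt(sqrt(sum((frag$xyz[i, ] - frag$xyz[j, ])^2)), 1.5)
    }
    # C-alphas stay near their path positions
    ca <- frag$xyz[frag$atoms$atom == "CA", ]
    expect_lt(max(sqrt(rowSums((ca - P)^2))), D / 2)
  }
  # glycine-only linkers have no side-chain atoms even when requested
  fragG <- place_all_atoms(P, linker_spec("GGGGG", spec$start, spec$end,
                                          far_obstacle()),
                           seed = 1, side_chains = TRUE)
  expect_false("CB" %in% fragG$atoms$atom)
  fragS <- place_all_atoms(P, spec, seed = 1, side_chains = TRUE)
  expect_true("CB" %in% fragS$atoms$atom)
})

test_that("termini grow clash-free with distinct conformations per seed", {
  tc <- toy_conditions(seed = 3, linker = 2)
  expect_identical(attach_termini(tc$mol, "", "", seed = 1), tc$mol)
  g1 <- attach_termini(tc$mol, "GG", "GGG", seed = 1)
  expect_equal(n_atoms(g1), n_atoms(tc$mol) + 5)
  expect_equal(sum(g1$rigid_group == 0), sum(tc$mol$rigid_group == 0) + 5)
  new1 <- g1$xyz[(n_atoms(tc$mol) + 1):n_atoms(g1), , drop = FALSE]
  g2 <- attach_termini(tc$mol, "GG", "GGG", seed = 2)
  new2 <- g2$xyz[(n_atoms(tc$mol) + 1):n_atoms(g2), , drop = FALSE]
  expect_gt(sqrt(mean((new1 - new2)^2)), 1)
  expect_lt(excluded_volume(g1), 1e-8)
})

test_that("bead linkers reach ideal spacing, zero clash and stay connected", {
  mol <- make_two_domain_system(two_domain_spec(seed = 3))
  for (s in 1:5) {
    lm <- add_bead_linker(mol, 6, seed = s)
    flex <- which(lm$rigid_group == 0)
    expect_equal(length(flex), 6)
    r <- range(lm$atoms$resid[flex])
    sel <- lm$atoms$resid >= r[1] - 1 & lm$atoms$resid <= r[2] + 1
    seg <- lm$xyz[order(lm$atoms$resid), ][sort(lm$atoms$resid) %in%
                                             (r[1] - 1):(r[2] + 1), ]
    d <- sqrt(rowSums(diff(seg)^2))
    expect_lt(max(abs(d - 3.86)), 0.1)
    expect_lt(excluded_volume(lm), 1e-8)
  }
  # distinct seeds explore distinct conformations
  l1 <- add_bead_linker(mol, 6, seed = 1)
  l2 <- add_bead_linker(mol, 6, seed = 2)
  expect_gt(sqrt(mean((l1$xyz[l1$rigid_group == 0, ] -
                         l2$xyz[l2$rigid_group == 0, ])^2)), 0.3)
})
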