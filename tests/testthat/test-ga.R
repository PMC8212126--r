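# structured pool: a family of decoys plus two planted extreme states
# (compact and extended), whose 70/30 mixture is the "experimental" data
planted_pool <- function(n_decoys = 48, noise_seed = 9, a = 0.01) {
  specs <- c(lapply(seq_len(n_decoys), function(s)
    two_domain_spec(seed = s, separation = 20 + 10 * (s - 1) / (n_decoys - 1))),
    list(two_domain_spec(seed = 101, separation = 12),
         two_domain_spec(seed = 102, separation = 45)))
  mols <- lapply(specs, make_two_domain_system)
  q <- seq(0.02, 0.3, length.out = 60)
  w <- c(rep(0, n_decoys), 0.7, 0.3)
  make_profile_pool(mols, w, q, noise = noise_spec(a = a, seed = noise_seed))
}

test_that("the mixture chi-square fits weights and scale by nonnegative least squares", {
  q <- seq(0.02, 0.25, length.out = 40)
  mols <- lapply(1:3, function(s) make_two_domain_system(two_domain_spec(seed = s)))
  Im <- vapply(mols, function(m) compute_profile(m, q)$intensity,
               numeric(40))
  # k = 1, member identical to the data: exact fit at scale 1
  exact <- profile_pool(Im, saxs_profile(q, Im[, 2], 0.01 * Im[, 2]))
  sol <- ensemble_chi2(exact, 2)
  expect_equal(sol$chi2, 0, tolerance = 1e-12)
  expect_equal(sol$scale, 1, tolerance = 1e-9)
  expect_equal(unname(sol$weights), 1)

  # noise-free 70/30 mixture recovers exactly
  mix <- profile_pool(Im, saxs_profile(q, 0.7 * Im[, 1] + 0.3 * Im[, 3],
                                       0.01 * Im[, 1]))
  sol2 <- ensemble_chi2(mix, c(1, 3))
  expect_equal(unname(sol2$weights), c(0.7, 0.3), tolerance = 1e-6)
  expect_lt(sol2$chi2, 1e-10)

  # permutation invariance, and duplicating a member splits its weight
  sol3 <- ensemble_chi2(mix, c(3, 1))
  expect_equal(sol3$chi2, sol2$chi2, tolerance = 1e-12)
  pool_dup <- profile_pool(cbind(Im, Im[, 1]), mix$exp)
  sol4 <- ensemble_chi2(pool_dup, c(1, 3, 4))
  expect_equal(sol4$chi2, sol2$chi2, tolerance = 1e-8)
  expect_equal(unname(sol4$weights["1"] + sol4$weights["4"]), 0.7,
               tolerance = 1e-6)
  expect_equal(sum(sol4$weights), 1, tolerance = 1e-9)
})

test_that("the fitted mixture matches a dense simplex-grid oracle", {
  set.seed(4)
  q <- seq(0.02, 0.25, length.out = 40)
  mols <- lapply(4:6, function(s) make_two_domain_system(two_domain_spec(seed = s)))
  Im <- vapply(mols, function(m) compute_profile(m, q)$intensity, numeric(40))
  target <- 0.45 * Im[, 1] + 0.35 * Im[, 2] + 0.2 * Im[, 3]
  s <- 0.01 * target
  pool <- profile_pool(Im, saxs_profile(q, target + rnorm(40, 0, s), s))
  fit <- ensemble_chi2(pool, 1:3)
  # exhaustive scan over the weight simplex at 0.01 resolution, scale
  # profiled out in closed form per grid point
  best <- Inf
  for (w1 in seq(0, 1, by = 0.01)) for (w2 in seq(0, 1 - w1, by = 0.01)) {
    m <- Im %*% c(w1, w2, 1 - w1 - w2)
    sc <- sum(pool$exp$intensity * m / s^2) / sum(m^2 / s^2)
    x2 <- mean(((sc * m - pool$exp$intensity) / s)^2)
    if (x2 < best) best <- x2
  }
  expect_lte(fit$chi2, best + 1e-9)
  expect_lt(abs(fit$chi2 - best), 0.05)
})

test_that("enlarging the member set can never worsen the optimal fit", {
  pool <- planted_pool(n_decoys = 8)
  set.seed(2)
  for (i in 1:5) {
    base <- sample(pool$ids, 3)
    extra <- sample(setdiff(pool$ids, base), 1)
    expect_lte(ensemble_chi2(pool, c(base, extra))$chi2,
               ensemble_chi2(pool, base)$chi2 + 1e-9)
  }
})

test_that("the GA finds a planted single conformer and beats random search", {
  pool <- planted_pool(n_decoys = 18)
  # one conformer equals the data exactly: k = 1 must find the needle
  exp_solo <- saxs_profile(pool$exp$q, pool$intensities[, 19],
                           pool$exp$error)
  solo <- profile_pool(pool$intensities[, c(1:10, 19)], exp_solo,
                       ids = c(1:10, 19))
  for (sd in 1:3) {
    sol <- run_ga(solo, ga_config(k = 1, generations = 30, population = 30,
                                  seed = sd))
    expect_equal(unname(sol$members), 19)
    expect_lt(sol$chi2, 1e-10)
  }
  # exhaustive-scan sanity at k = 1
  scan <- vapply(solo$ids, function(id) ensemble_chi2(solo, id)$chi2,
                 numeric(1))
  expect_equal(solo$ids[which.min(scan)], 19)

  # GA never loses to a same-budget random member-set baseline
  cfg <- ga_config(k = 3, generations = 40, population = 50, seed = 7)
  sol <- run_ga(pool, cfg)
  set.seed(31)
  base <- min(vapply(1:1000, function(i)
    ensemble_chi2(pool, sample(pool$ids, 3))$chi2, numeric(1)))
  expect_lte(sol$chi2, base + 1e-12)
})

test_that("a planted 70/30 two-state mixture is recovered at k = 3", {
  pool <- planted_pool()
  sol <- run_ga(pool, ga_config(k = 3, generations = 150, population = 150,
                                seed = 1))
  w <- sol$weights
  expect_lt(abs(sum(w[names(w) == "49"]) - 0.7), 0.05)
  expect_lt(abs(sum(w[names(w) == "50"]) - 0.3), 0.05)
  expect_lt(sum(w[!names(w) %in% c("49", "50")]), 0.05)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # group bookkeeping: per-family weight sums
  groups <- c(rep("decoy", 48), "open", "closed")
  names(groups) <- as.character(1:50)
  gw <- group_weights(sol, groups)
  expect_lt(abs(gw[["open"]] - 0.7), 0.05)
})

test_that("chi-square is non-increasing in ensemble size and flat for a single source", {
  pool <- planted_pool(n_decoys = 18)
  # single-source data: already fit at k = 1, flat afterwards
  exp_solo <- saxs_profile(pool$exp$q, pool$intensities[, 19],
                           pool$exp$error)
  solo <- profile_pool(pool$intensities, exp_solo)
  cfg <- ga_config(generations = 40, population = 60, repeats = 2, seed = 3)
  tab <- size_scan(solo, c(1, 2, 3), cfg)
  expect_lt(tab$chi2_min[1], 1e-8)
  expect_true(all(tab$chi2_min < 1e-8))
  expect_equal(names(tab), c("k", "chi2_mean", "chi2_sd", "chi2_min"))
  # planted two-state mixture: large drop from k = 1 to k = 2, then plateau
  tab2 <- size_scan(planted_pool(n_decoys = 18), c(1, 2, 3), cfg)
  expect_gt(tab2$chi2_min[1] / tab2$chi2_min[2], 3)
  expect_lt(abs(tab2$chi2_min[3] - tab2$chi2_min[2]),
            0.5 * tab2$chi2_min[2] + 0.5)
})
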