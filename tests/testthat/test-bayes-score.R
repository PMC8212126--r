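mk_prof <- function(I, s) saxs_profile(seq_along(I) / 100, I, s)

test_that("chi-square matches hand evaluation and scales quadratically in the errors", {
  p <- mk_prof(c(1, 2), c(1, 1))
  expect_equal(chi_square(p, c(1, 1), gamma = 1), 0.5)
  expect_equal(chi_square(p, c(0.5, 1), gamma = 2), 0)
  p2 <- mk_prof(c(1, 2), c(2, 2))
  expect_equal(chi_square(p2, c(1, 1), 1), 0.5 / 4)
  expect_error(chi_square(p, c(1, 1, 1), 1), "mismatch")
})

test_that("the maximum-posterior scale factor is the weighted least-squares optimum", {
  m <- c(3, 1, 4, 1, 5)
  p <- mk_prof(2 * m, rep(0.5, 5))
  expect_equal(map_gamma(p, m), 2)
  expect_equal(map_gamma(mk_prof(m, rep(1, 5)), m), 1)

  set.seed(1)
  m <- exp(rnorm(50)); s <- runif(50, 0.5, 2)
  p <- mk_prof(1.7 * m + rnorm(50, 0, s), s)
  gh <- map_gamma(p, m)
  # dense 1-D scan oracle
  grid <- seq(gh - 0.5, gh + 0.5, length.out = 100001)
  x2 <- vapply(grid, function(g) chi_square(p, m, g), numeric(1))
  expect_lt(abs(grid[which.min(x2)] - gh), 1e-5 + diff(grid[1:2]))
  expect_error(map_gamma(p, rep(0, 50)), "degenerate")
  expect_warning(map_gamma(mk_prof(-m, s), m), "non-positive")
})

test_that("the error-scale optimum is sqrt(chi^2), floored on exact fits", {
  expect_equal(map_sigma(4), 2)
  expect_equal(map_sigma(1), 1)
  expect_message(out <- map_sigma(0), "floored")
  expect_equal(out, 1e-6)
  # numeric oracle: stationary point of the likelihood in sigma at
  # chi^2 = 2.7, located by root-finding on a central-difference gradient
  M <- 40; x2 <- 2.7
  f <- function(s) M / (2 * s^2) * x2 + M * log(s)
  fd <- function(s, h = 1e-5) (f(s + h) - f(s - h)) / (2 * h)
  num <- stats::uniroot(fd, c(0.1, 10), tol = 1e-12)$root
  expect_lt(abs(num - sqrt(2.7)), 1e-8)
  expect_equal(map_sigma(2.7), sqrt(2.7))
})

test_that("the negative log likelihood has the stated value and shape", {
  p <- mk_prof(c(1, 2, 3, 4), rep(1, 4))
  m <- c(1, 2, 3, 4) + c(1, -1, 1, -1)  # chi^2 = 1 at gamma = 1
  expect_equal(chi_square(p, m, 1), 1)
  expect_equal(neg_log_likelihood(p, m, 1, 1), 4 / 2)
  # at the sigma optimum the value is M/2 (1 + log chi^2)
  p2 <- mk_prof(c(2, 4, 3, 1), rep(0.7, 4))
  m2 <- c(1.4, 4.4, 2.2, 1.5)
  g <- map_gamma(p2, m2)
  x2 <- chi_square(p2, m2, g)
  sh <- map_sigma(x2)
  expect_equal(neg_log_likelihood(p2, m2, g, sh),
               4 / 2 * (1 + log(x2)), tolerance = 1e-12)
  # strictly increasing beyond the optimum
  ss <- sh * c(1.1, 1.5, 3, 10)
  vals <- vapply(ss, function(s) neg_log_likelihood(p2, m2, g, s), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(neg_log_likelihood(p, m, 1, 0), "positive")
})

test_that("the marginal score is M/2 log chi^2 and ranks like the full score", {
  p <- mk_prof(c(1, 2, 3, 4), rep(1, 4))
  m <- c(1, 2, 3, 4) + c(1, -1, 1, -1)
  expect_equal(marginal_score(p, m, 1), 0)   # chi^2 = 1 -> log 1
  mA <- c(1, 2, 3, 4) + 2 * c(1, -1, 1, -1)  # chi^2 = 4
  expect_gt(marginal_score(p, mA, 1), marginal_score(p, m, 1))
  # equals the full score at the sigma optimum up to the constant M/2
  g <- map_gamma(p, mA)
  x2 <- chi_square(p, mA, g)
  expect_equal(marginal_score(p, mA, g),
               neg_log_likelihood(p, mA, g, map_sigma(x2)) - 4 / 2,
               tolerance = 1e-12)
})

test_that("gamma-hat and sigma-hat jointly minimize the likelihood (numeric oracle)", {
  set.seed(3)
  for (rep in 1:10) {
    M <- sample(20:80, 1)
    m <- exp(rnorm(M, 0, 0.5))
    s <- runif(M, 0.3, 1.5)
    p <- mk_prof(runif(1, 0.5, 3) * m + rnorm(M, 0, s), s)
    gh <- map_gamma(p, m)
    sh <- map_sigma(chi_square(p, m, gh))
    # the likelihood is separable: locate the stationary point in each
    # parameter by root-finding on central-difference gradients
    gnum <- stats::uniroot(function(g)
      (chi_square(p, m, g + 1e-5) - chi_square(p, m, g - 1e-5)) / 2e-5,
      gh + c(-2, 2), tol = 1e-12)$root
    snum <- stats::uniroot(function(s2)
      (neg_log_likelihood(p, m, gnum, s2 + 1e-5) -
         neg_log_likelihood(p, m, gnum, s2 - 1e-5)) / 2e-5,
      c(1e-2, 50), tol = 1e-12)$root
    expect_lt(abs(gnum - gh), 1e-8)
    expect_lt(abs(snum - sh), 1e-8)
    expect_lt(abs(sh^2 - chi_square(p, m, gh)), 1e-12)
  }
})

test_that("the automatic weight is M / 2 sigma^2 and doubles when chi^2 halves", {
  expect_equal(restraint_weight(100, 1), 50)
  x2 <- 3.6; M <- 77
  w1 <- restraint_weight(M, map_sigma(x2))
  w2 <- restraint_weight(M, map_sigma(x2 / 2))
  expect_equal(w2 / w1, 2, tolerance = 1e-12)
})

test_that("the staged c1/c2 grid search recovers generating values and respects bounds", {
  mol <- make_two_domain_system(two_domain_spec(seed = 6))
  q <- seq(0.02, 0.35, length.out = 120)
  hw <- hydration_surface_weights(mol)
  m <- compute_profile(mol, q, c1 = 1.02, c2 = 1.5, hyd_w = hw)$intensity
  prof <- saxs_profile(q, m, 1e-4 * m + 1e-6 * m[1])
  opt <- optimize_c1_c2(prof, mol)
  # within the final grid spacing ((range / 10) / 10 per parameter; the
  # search cannot localize the optimum below its own quantization)
  expect_lt(abs(opt$c1 - 1.02), 0.1 / 100 * 1.05)
  expect_lt(abs(opt$c2 - 1.5), 6 / 100 * 1.05)
  expect_equal(opt$sigma, sqrt(opt$chi2))
  expect_equal(nrow(opt$grid), 121)
  # generating values on the range boundary: the refinement grids stay
  # clamped to the admissible ranges
  m2 <- compute_profile(mol, q, c1 = 1.05, c2 = 0, hyd_w = hw)$intensity
  prof2 <- saxs_profile(q, m2, 1e-4 * m2 + 1e-6 * m2[1])
  opt2 <- optimize_c1_c2(prof2, mol)
  expect_lte(opt2$c1, 1.05)
  expect_gte(opt2$c1, 0.95)
  expect_lte(opt2$c2, 4); expect_gte(opt2$c2, -2)
})

test_that("the fit front end exposes the usual modelling methods", {
  tc <- toy_conditions(seed = 9)
  fit <- saxs_fit(tc$mol, tc$prof, fit_c1c2 = FALSE)
  expect_s3_class(fit, "saxs_fit")
  expect_named(coef(fit), c("gamma", "sigma", "c1", "c2"))
  expect_equal(fit$sigma^2, fit$chi2, tolerance = 1e-12)
  expect_equal(fitted(fit), fit$gamma * fit$m)
  expect_equal(residuals(fit),
               (tc$prof$intensity - fitted(fit)) / tc$prof$error)
  expect_equal(predict(fit), fitted(fit))
  newq <- c(0.05, 0.1)
  expect_equal(predict(fit, newq),
               fit$gamma * compute_profile(tc$mol, newq)$intensity)
  expect_output(print(fit), "chi\\^2")
  expect_output(summary(fit), "weighted residuals")
  expect_equal(fit$weight, nrow(tc$prof) / (2 * fit$sigma^2))
})
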