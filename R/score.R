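# The Bayesian SAXS restraint.
#
# The likelihood of an experimental profile I(q_i) +/- s(q_i), i = 1..M,
# given a structure with model intensities m_i and nuisance parameters
# (scale factor gamma, error scale sigma) is
#
#   -log p = (M / 2 sigma^2) * chi^2(gamma)  +  M * log(sigma),
#   chi^2(gamma) = (1/M) sum_i ((I_i - gamma m_i) / s_i)^2.
#
# Both nuisance parameters have closed-form optima: gamma-hat is the
# weighted least-squares scale and sigma-hat^2 = chi^2(gamma-hat).  The
# factor M / (2 sigma^2) is the effective weight of the restraint; because
# sigma tracks the current fit quality it anneals automatically during
# structure determination.  Marginalizing sigma (Jeffreys prior 1/sigma)
# yields the parameter-free score (M/2) log chi^2, a strictly increasing
# transform of chi^2.

calc_vec <- function(calc) {
  if (inherits(calc, "computed_profile")) calc$intensity else as.numeric(calc)
}

#' Reduced chi-square between experimental and computed intensities
#'
#' `chi^2 = (1/M) sum_i ((I_i - gamma m_i) / s_i)^2` on a linear intensity
#' scale with the experimental errors.
#'
#' @param exp a [saxs_profile].
#' @param calc computed intensities on `exp$q` (numeric vector or
#'   `computed_profile`).
#' @param gamma scale factor applied to `calc`.
#' @return nonnegative scalar; 0 iff the scaled fit is exact.
#' @export
chi_square <- function(exp, calc, gamma = 1) {
  m <- calc_vec(calc)
  if (length(m) != nrow(exp)) stop("profile length mismatch")
  mean(((exp$intensity - gamma * m) / exp$error)^2)
}

#' Maximum-posterior scale factor
#'
#' Closed-form weighted least-squares optimum
#' `gamma-hat = sum(I m / s^2) / sum(m^2 / s^2)`, the minimizer of
#' [chi_square()] over gamma.  A negative optimum (anti-correlated model)
#' triggers a data-quality warning.
#'
#' @inheritParams chi_square
#' @return scalar gamma-hat.
#' @export
map_gamma <- function(exp, calc) {
  m <- calc_vec(calc)
  if (length(m) != nrow(exp)) stop("profile length mismatch")
  den <- sum(m^2 / exp$error^2)
  if (den <= 0) stop("degenerate model intensities (all zero)")
  g <- sum(exp$intensity * m / exp$error^2) / den
  if (g <= 0) warning("non-positive optimal scale factor; model anti-correlates with data")
  g
}

#' Maximum-likelihood error scale
#'
#' The stationary point of the negative log likelihood in sigma is
#' `sigma-hat = sqrt(chi^2)`.  An exact fit (chi^2 = 0) returns the
#' configured floor.
#'
#' @param chi2 chi-square at the current (usually optimal) gamma.
#' @param sigma_min floor returned for an exact fit.
#' @return scalar sigma-hat > 0.
#' @export
map_sigma <- function(chi2, sigma_min = 1e-6) {
  if (chi2 < 0) stop("chi2 must be nonnegative")
  if (chi2 == 0) {
    message("exact fit: sigma floored at ", sigma_min)
    return(sigma_min)
  }
  sqrt(chi2)
}

#' Negative log likelihood of a profile given a structure
#'
#' `(M / 2 sigma^2) chi^2(gamma) + M log(sigma)`.
#'
#' @inheritParams chi_square
#' @param sigma error scale, > 0.
#' @return scalar score (lower is better).
#' @export
neg_log_likelihood <- function(exp, calc, gamma, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  M <- nrow(exp)
  M / (2 * sigma^2) * chi_square(exp, calc, gamma) + M * log(sigma)
}

#' Marginalized (sigma-free) Bayesian score
#'
#' `(M/2) log chi^2(gamma)`: the negative log posterior after integrating
#' the error scale out under a Jeffreys prior, up to an additive constant.
#' Equals the full score at sigma = sigma-hat minus M/2, so both rank
#' structures identically.
#'
#' @inheritParams chi_square
#' @param sigma_min floor substituted for chi = 0 fits.
#' @return scalar score.
#' @export
marginal_score <- function(exp, calc, gamma = NULL, sigma_min = 1e-6) {
  if (is.null(gamma)) gamma <- map_gamma(exp, calc)
  x2 <- chi_square(exp, calc, gamma)
  if (x2 == 0) x2 <- sigma_min^2
  nrow(exp) / 2 * log(x2)
}

#' Automatic restraint weight
#'
#' `M / (2 sigma^2)`: the factor multiplying chi^2 in the score.  With
#' sigma at its optimum this is `M / (2 chi^2)`, so the data's influence
#' grows as the fit improves (automatic annealing).
#'
#' @param M number of profile points.
#' @param sigma error scale.
#' @return scalar weight > 0.
#' @export
restraint_weight <- function(M, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  M / (2 * sigma^2)
}

#' Staged grid search for the forward-model parameters c1 and c2
#'
#' Three rounds of an 11 x 11 grid: the full admissible ranges first; then a
#' grid centred on the best pair whose total span covers four cells (2 x 2)
#' of the previous grid; then a third round with half that span.  Before
#' every grid evaluation gamma and sigma are set to their maximum-posterior
#' values, so each cell is scored by the marginalized criterion (equivalently
#' its chi^2).  Ties keep the first-encountered cell in row-major (c1-major)
#' order; refinement grids are clipped to the admissible ranges.
#'
#' @param exp a [saxs_profile]; the model is evaluated on `exp$q`.
#' @param mol a [saxs_molecule] (heavy atoms or beads).
#' @param c1_range,c2_range admissible ranges.
#' @param grid_n points per grid side.
#' @return list with `c1`, `c2`, `gamma`, `sigma`, `chi2` and the evaluated
#'   grid of the first round (`grid`, a data frame with c1, c2, chi2).
#' @export
optimize_c1_c2 <- function(exp, mol, c1_range = c(0.95, 1.05),
                           c2_range = c(-2, 4), grid_n = 11) {
  hyd_w <- hydration_surface_weights(mol)
  D <- as.matrix(stats::dist(
    if (!mol$bead && any(mol$atoms$element == "H"))
      mol$xyz[mol$atoms$element != "H", , drop = FALSE] else mol$xyz))
  molh <- if (!mol$bead && any(mol$atoms$element == "H"))
    subset_molecule(mol, which(mol$atoms$element != "H")) else mol
  q <- exp$q
  eval_cell <- function(c1, c2) {
    Fm <- form_factor_matrix(molh, q, c1, c2, hyd_w)
    m <- debye_sum(Fm, D, q)
    g <- suppressWarnings(map_gamma(exp, m))
    x2 <- chi_square(exp, m, g)
    list(chi2 = x2, gamma = g)
  }
  run_grid <- function(c1s, c2s) {
    best <- NULL
    cells <- expand.grid(c2 = c2s, c1 = c1s)[, c("c1", "c2")]  # c1-major
    cells$chi2 <- NA_real_
    for (r in seq_len(nrow(cells))) {
      res <- tryCatch(eval_cell(cells$c1[r], cells$c2[r]),
                      error = function(e) NULL)
      if (is.null(res) || !is.finite(res$chi2)) {
        warning("non-finite score at c1=", cells$c1[r], " c2=", cells$c2[r],
                "; cell skipped")
        next
      }
      cells$chi2[r] <- res$chi2
      if (is.null(best) || res$chi2 < best$chi2)
        best <- c(res, list(c1 = cells$c1[r], c2 = cells$c2[r]))
    }
    if (is.null(best)) stop("all grid cells non-finite")
    list(best = best, cells = cells)
  }
  clamp_grid <- function(center, half_width, rng, n) {
    lo <- max(center - half_width, rng[1])
    hi <- min(center + half_width, rng[2])
    seq(lo, hi, length.out = n)
  }
  c1s <- seq(c1_range[1], c1_range[2], length.out = grid_n)
  c2s <- seq(c2_range[1], c2_range[2], length.out = grid_n)
  step1 <- c(diff(c1_range), diff(c2_range)) / (grid_n - 1)
  r1 <- run_grid(c1s, c2s)
  b <- r1$best
  # round 2: total span = 2 cells of round 1 (a 2 x 2 block)
  r2 <- run_grid(clamp_grid(b$c1, step1[1], c1_range, grid_n),
                 clamp_grid(b$c2, step1[2], c2_range, grid_n))
  b <- r2$best
  # round 3: half the span of round 2
  r3 <- run_grid(clamp_grid(b$c1, step1[1] / 2, c1_range, grid_n),
                 clamp_grid(b$c2, step1[2] / 2, c2_range, grid_n))
  b <- r3$best
  list(c1 = b$c1, c2 = b$c2, gamma = b$gamma,
       sigma = map_sigma(b$chi2), chi2 = b$chi2, grid = r1$cells)
}
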