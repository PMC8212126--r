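# Model-fitting front end: fit the Bayesian SAXS restraint's nuisance
# parameters for one structure against one experimental profile, returning
# a classed object with the usual accessor methods.

#' Fit a structure to an experimental SAXS profile
#'
#' Evaluates the forward model on the experimental q grid and sets the
#' nuisance parameters to their maximum-posterior values: the scale factor
#' gamma and error scale sigma in closed form, and (optionally) the
#' excluded-volume and hydration parameters c1, c2 by the staged grid
#' search of [optimize_c1_c2()].
#'
#' @param mol a [saxs_molecule].
#' @param profile a [saxs_profile] (experimental or synthetic).
#' @param fit_c1c2 optimize c1/c2 by grid search (`TRUE`) or hold them at
#'   `c1`, `c2` (`FALSE`).
#' @param c1,c2 forward-model parameters used when `fit_c1c2 = FALSE`.
#' @param sigma_min floor for the error scale on exact fits.
#' @return an object of class `saxs_fit` with components `chi2`, `gamma`,
#'   `sigma`, `c1`, `c2`, `weight` (`M / 2 sigma^2`), `score` (negative log
#'   likelihood at the optimum), `marginal` (the sigma-free score), `M`,
#'   the computed intensities `m`, and the inputs.
#' @examples
#' sys <- make_two_domain_system(two_domain_spec(seed = 1))
#' prof <- simulate_profile(sys, seq(0.02, 0.3, length.out = 60),
#'                          noise = noise_spec(a = 0.01, seed = 2))
#' fit <- saxs_fit(sys, prof, fit_c1c2 = FALSE)
#' coef(fit)
#' @export
saxs_fit <- function(mol, profile, fit_c1c2 = TRUE, c1 = 1, c2 = 0,
                     sigma_min = 1e-6) {
  stopifnot(inherits(mol, "saxs_molecule"), inherits(profile, "saxs_profile"))
  if (fit_c1c2) {
    opt <- optimize_c1_c2(profile, mol)
    c1 <- opt$c1; c2 <- opt$c2
  }
  calc <- compute_profile(mol, profile$q, c1 = c1, c2 = c2)
  gamma <- suppressWarnings(map_gamma(profile, calc))
  chi2 <- chi_square(profile, calc, gamma)
  sigma <- suppressMessages(map_sigma(chi2, sigma_min))
  M <- nrow(profile)
  structure(list(chi2 = chi2, gamma = gamma, sigma = sigma, c1 = c1, c2 = c2,
                 weight = restraint_weight(M, sigma),
                 score = neg_log_likelihood(profile, calc, gamma, sigma),
                 marginal = marginal_score(profile, calc, gamma),
                 M = M, m = calc$intensity, profile = profile,
                 mol = mol, fit_c1c2 = fit_c1c2),
            class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, digits = 4, ...) {
  cat("Bayesian SAXS fit\n")
  cat(sprintf("  chi^2  = %.*g   (M = %d points)\n", digits, x$chi2, x$M))
  cat(sprintf("  gamma  = %.*g   sigma = %.*g   weight M/2sigma^2 = %.*g\n",
              digits, x$gamma, digits, x$sigma, digits, x$weight))
  cat(sprintf("  c1     = %.*g   c2 = %.*g%s\n", digits, x$c1, digits, x$c2,
              if (x$fit_c1c2) "   (grid-optimized)" else "   (fixed)"))
  invisible(x)
}

#' @export
summary.saxs_fit <- function(object, ...) {
  res <- residuals(object)
  cat("Bayesian SAXS fit\n\n")
  print(object)
  cat(sprintf("  score (neg. log likelihood) = %.6g\n", object$score))
  cat(sprintf("  marginal score (M/2 log chi^2) = %.6g\n", object$marginal))
  cat(sprintf("  weighted residuals: mean %.3g, sd %.3g, max |r| %.3g\n",
              mean(res), stats::sd(res), max(abs(res))))
  invisible(object)
}

#' @export
coef.saxs_fit <- function(object, ...) {
  c(gamma = object$gamma, sigma = object$sigma,
    c1 = object$c1, c2 = object$c2)
}

#' @export
fitted.saxs_fit <- function(object, ...) object$gamma * object$m

#' Weighted residuals of a SAXS fit
#' @param object a `saxs_fit`.
#' @param ... unused.
#' @return `(I - gamma m) / s` per profile point.
#' @export
residuals.saxs_fit <- function(object, ...) {
  (object$profile$intensity - object$gamma * object$m) / object$profile$error
}

#' Predict model intensities on a new q grid
#' @param object a `saxs_fit`.
#' @param q optional new grid (defaults to the experimental grid).
#' @param ... unused.
#' @return numeric vector `gamma * m(q)`.
#' @export
predict.saxs_fit <- function(object, q = NULL, ...) {
  if (is.null(q)) return(fitted(object))
  object$gamma * compute_profile(object$mol, q, c1 = object$c1,
                                 c2 = object$c2)$intensity
}

#' @export
plot.saxs_fit <- function(x, log = "y", ...) {
  p <- x$profile
  graphics::plot(p$q, p$intensity, log = log, pch = 20, cex = 0.5,
                 xlab = expression(q ~ (ring(A)^-1)), ylab = "I(q)",
                 main = sprintf("chi^2 = %.3g", x$chi2), ...)
  graphics::arrows(p$q, p$intensity - p$error, p$q, p$intensity + p$error,
                   length = 0, col = "grey70")
  graphics::lines(p$q, fitted(x), col = "red3", lwd = 2)
  invisible(x)
}
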