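# Genetic-algorithm selection of a minimal weighted conformer ensemble.
# A candidate is a set of k conformer ids; its fitness is the chi-square
# of the best-fitting nonnegative mixture of the members' profiles
# (weights and a global scale fitted by nonnegative least squares) against
# the experimental profile:
#
#   chi^2 = (1/M) sum_i ((Icalc(q_i) - Iexp(q_i)) / s(q_i))^2,
#   Icalc = scale * sum_k w_k I_k,  w_k >= 0,  sum w_k = 1.

#' Best-fit mixture chi-square of an ensemble
#'
#' Jointly fits nonnegative member weights and a global scale by
#' error-weighted nonnegative least squares and returns the resulting
#' chi-square.  With `fit_scale = FALSE` the weights are renormalized to
#' sum to 1 and no scale is applied (the literal unscaled criterion).
#'
#' @param pool a [profile_pool].
#' @param members conformer ids (subset of `pool$ids`).
#' @param fit_scale fit a global scale factor alongside the weights.
#' @return list: `chi2`, `scale`, `weights` (named by member id, summing
#'   to 1), `members`.
#' @export
ensemble_chi2 <- function(pool, members, fit_scale = TRUE) {
  stopifnot(inherits(pool, "profile_pool"), length(members) >= 1)
  idx <- match(members, pool$ids)
  if (any(is.na(idx))) stop("unknown conformer id")
  A <- pool$intensities[, idx, drop = FALSE]
  s <- pool$exp$error
  b <- pool$exp$intensity / s
  Aw <- A / s
  coef <- tryCatch(pracma::lsqnonneg(Aw, b)$x, error = function(e) NULL)
  if (is.null(coef) || sum(coef) <= 0) {
    # degenerate (e.g. identical members): uniform split, scale by 1-D fit
    warning("degenerate ensemble fit; falling back to uniform weights")
    w <- rep(1 / length(idx), length(idx))
    m <- drop(A %*% w)
    sc <- sum(pool$exp$intensity * m / s^2) / sum(m^2 / s^2)
    coef <- sc * w
  }
  total <- sum(coef)
  w <- coef / total
  if (fit_scale) {
    calc <- drop(A %*% coef)
    scale <- total
  } else {
    calc <- drop(A %*% w)
    scale <- 1
  }
  chi2 <- mean(((calc - pool$exp$intensity) / s)^2)
  list(chi2 = chi2, scale = scale,
       weights = stats::setNames(w, members), members = members)
}

#' Genetic-algorithm configuration
#'
#' @param k ensemble size (members per candidate).
#' @param generations GA steps.
#' @param population candidates per generation.
#' @param crossover_rate probability an offspring is produced by member-set
#'   crossover rather than cloning.
#' @param mutation expected member replacements per offspring
#'   (`mutation_mode = "per_offspring"`) or per-member replacement
#'   probability (`"per_gene"`).
#' @param mutation_mode see `mutation`.
#' @param repeats independent GA repetitions for [size_scan()].
#' @param seed RNG seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(k = 3, generations = 1000, population = 1000,
                      crossover_rate = 0.8, mutation = 1,
                      mutation_mode = c("per_offspring", "per_gene"),
                      repeats = 5, seed = 1) {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(k >= 1, generations >= 1, population >= 2,
            crossover_rate >= 0, crossover_rate <= 1, mutation >= 0)
  structure(list(k = as.integer(k), generations = as.integer(generations),
                 population = as.integer(population),
                 crossover_rate = crossover_rate, mutation = mutation,
                 mutation_mode = mutation_mode, repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Evolve a minimal ensemble fitting the experimental profile
#'
#' Tournament selection (size 2), member-id crossover at the configured
#' rate, mutation (expected one id replacement per offspring by default)
#' and elitism of the best candidate; fitness is the negative of
#' [ensemble_chi2()].  Seeded and reproducible; fitness values are
#' memoized over member sets.
#'
#' @param pool a [profile_pool].
#' @param config a [ga_config()].
#' @param fit_scale passed to [ensemble_chi2()].
#' @return list of class `ensemble_solution`: `members`, `weights`,
#'   `scale`, `chi2`, and the best-chi2 trace per generation.
#' @export
run_ga <- function(pool, config = ga_config(), fit_scale = TRUE) {
  n <- length(pool$ids)
  k <- config$k
  if (n < k) stop("pool smaller than ensemble size")
  resample <- function(x, size) x[sample.int(length(x), size)]
  memo <- new.env(parent = emptyenv())
  fitness <- function(members) {
    key <- paste(sort(members), collapse = ",")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- suppressWarnings(ensemble_chi2(pool, members, fit_scale))$chi2
    memo[[key]] <- val
    val
  }
  with_seed(config$seed, {
    popn <- replicate(config$population, resample(pool$ids, k),
                      simplify = FALSE)
    fit <- vapply(popn, fitness, numeric(1))
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      best <- which.min(fit)
      newpop <- vector("list", config$population)
      newpop[[1]] <- popn[[best]]           # elitism
      for (o in 2:config$population) {
        pick <- function() {
          c2 <- sample.int(config$population, 2)
          popn[[c2[which.min(fit[c2])]]]
        }
        p1 <- pick()
        child <- if (stats::runif(1) < config$crossover_rate) {
          p2 <- pick()
          geneset <- unique(c(p1, p2))
          if (length(geneset) >= k) resample(geneset, k) else
            c(geneset, resample(setdiff(pool$ids, geneset),
                                k - length(geneset)))
        } else p1
        nmut <- if (config$mutation_mode == "per_offspring")
          stats::rpois(1, config$mutation) else
            stats::rbinom(1, k, config$mutation)
        nmut <- min(nmut, k, n - k)
        if (nmut > 0) {
          slots <- sample.int(k, nmut)
          repl <- resample(setdiff(pool$ids, child), nmut)
          child[slots] <- repl
        }
        newpop[[o]] <- child
      }
      popn <- newpop
      fit <- vapply(popn, fitness, numeric(1))
      trace[g] <- min(fit)
    }
    best <- popn[[which.min(fit)]]
    sol <- suppressWarnings(ensemble_chi2(pool, best, fit_scale))
    structure(c(sol, list(trace = trace, config = config)),
              class = "ensemble_solution")
  })
}

#' @export
print.ensemble_solution <- function(x, ...) {
  cat(sprintf("Ensemble of %d conformers: chi^2 = %.4g, scale = %.4g\n",
              length(x$members), x$chi2, x$scale))
  w <- sort(x$weights, decreasing = TRUE)
  cat("  weights:", paste(sprintf("%s=%.3f", names(w), w), collapse = ", "),
      "\n")
  invisible(x)
}

#' Chi-square versus ensemble size
#'
#' Runs the GA `config$repeats` times (seeds offset from `config$seed`)
#' for each requested size and reports mean and sd of the best chi-square,
#' the shape of which shows where adding conformers stops improving the
#' fit.
#'
#' @param pool a [profile_pool].
#' @param sizes integer vector of ensemble sizes.
#' @param config base [ga_config()] (its `k` is overridden per size).
#' @return data frame with columns `k`, `chi2_mean`, `chi2_sd`, `chi2_min`.
#' @export
size_scan <- function(pool, sizes, config = ga_config()) {
  rows <- lapply(sizes, function(k) {
    x2 <- vapply(seq_len(config$repeats), function(r) {
      cfg <- config
      cfg$k <- as.integer(k)
      cfg$seed <- config$seed + 1000L * (r - 1L)
      run_ga(pool, cfg)$chi2
    }, numeric(1))
    data.frame(k = k, chi2_mean = mean(x2),
               chi2_sd = if (length(x2) > 1) stats::sd(x2) else 0,
               chi2_min = min(x2))
  })
  do.call(rbind, rows)
}

#' Sum ensemble weights per structural group
#'
#' @param solution an `ensemble_solution`.
#' @param groups named vector mapping conformer id to group label (e.g.
#'   from [som_groups()] via the pose assignment).
#' @return named numeric of per-group total weight.
#' @export
group_weights <- function(solution, groups) {
  g <- groups[as.character(solution$members)]
  tapply(solution$weights, g, sum)
}
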