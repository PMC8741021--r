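# Seeded generators for the data-generating processes used in the Monte
# Carlo experiments: standard-normal covariates, over-dispersed Poisson
# counts via the gamma-Poisson (negative binomial) construction, low-rank
# spatial Gaussian fields, and group random intercepts.

#' Standard-normal covariate matrix
#'
#' @param n,k Dimensions.
#' @param seed Optional integer seed (local to this call).
#' @return An `n x k` matrix of iid N(0, 1) draws.
#' @export
gen_covariates <- function(n, k, seed = NULL) {
  stopifnot(n >= 1, k >= 1)
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  matrix(stats::rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
}

#' Over-dispersed Poisson counts via the gamma-Poisson mixture
#'
#' Draws counts with mean `lambda_i` and variance `sigma2 * lambda_i`. For
#' `sigma2 = 1` draws are exactly Poisson. For `sigma2 > 1` the negative
#' binomial construction is used: with `nu_i = (sigma2 - 1)/lambda_i`, counts
#' are negative binomial with mean `lambda_i` and variance
#' `lambda_i + nu_i lambda_i^2 = sigma2 * lambda_i`, realised as a
#' gamma-Poisson mixture (gamma shape `1/nu_i`, mean `lambda_i`) because `nu`
#' varies per observation.
#'
#' @param lambda Positive mean vector.
#' @param sigma2 Over-dispersion parameter, `>= 1`.
#' @param seed Optional integer seed (local to this call).
#' @return Integer count vector.
#' @export
gen_odpoisson <- function(lambda, sigma2 = 1, seed = NULL) {
  if (any(lambda <= 0)) stop("'lambda' must be positive", call. = FALSE)
  if (length(sigma2) != 1L || is.na(sigma2) || sigma2 < 1) {
    stop("'sigma2' must be a single number >= 1", call. = FALSE)
  }
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  n <- length(lambda)
  if (sigma2 == 1) return(stats::rpois(n, lambda))
  nu <- (sigma2 - 1) / lambda
  shape <- 1 / nu
  g <- stats::rgamma(n, shape = shape, scale = lambda / shape)
  stats::rpois(n, g)
}

#' Draw a low-rank spatial Gaussian field
#'
#' Draws `s = B u` with `u ~ N(0, scale^2 I)` and `B` the low-rank GP basis
#' from [build_lowrank_gp_basis()], so the field covariance is `scale^2`
#' times the rank-truncated exponential kernel.
#'
#' @param coords N x 2 coordinates.
#' @param rank,range_h Passed to [build_lowrank_gp_basis()].
#' @param scale Field standard-deviation scale; 0 gives a zero field.
#' @param seed Optional integer seed.
#' @param basis Optional precomputed basis block (avoids refactorisation
#'   across replications).
#' @return Numeric field vector of length N.
#' @export
gen_spatial_field <- function(coords, rank = NULL, range_h = NULL, scale = 1,
                              seed = NULL, basis = NULL) {
  if (is.null(basis)) basis <- build_lowrank_gp_basis(coords, rank, range_h)
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  m <- ncol(basis$Z)
  drop(basis$Z %*% stats::rnorm(m, sd = scale))
}

#' Scenario configuration for Monte Carlo experiments
#'
#' Describes one data-generating condition: sample size, intercept,
#' coefficients, over-dispersion, and optional spatial-field or group-effect
#' components. Defaults reproduce the basic benchmarking condition: two
#' standard-normal covariates with a strong (2.0) and a weak (0.5)
#' coefficient, counts drawn over-dispersed Poisson with unit offsets.
#'
#' @param n Sample size.
#' @param beta0 Intercept (controls the share of zeros: smaller values give
#'   more zeros).
#' @param beta Non-intercept coefficients; its length sets the number of
#'   covariates.
#' @param sigma2 Over-dispersion, `>= 1`.
#' @param spatial Optional list with `rank`, `range_h`, `scale` enabling a
#'   low-rank spatial field on uniform unit-square coordinates.
#' @param groups Optional list with `n_groups`, `effect_sd` enabling a group
#'   random intercept.
#' @param offset Offset rule: scalar 1 (default) or a function `n -> z`.
#' @param seed Base integer seed; iteration `j` uses `seed + j`.
#' @param n_iter Number of Monte Carlo replications.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n = 200, beta0 = 0, beta = c(2, 0.5), sigma2 = 1,
                            spatial = NULL, groups = NULL, offset = 1,
                            seed = 1L, n_iter = 200L) {
  stopifnot(sigma2 >= 1, n_iter >= 1, n >= length(beta) + 2)
  if (!is.null(spatial)) {
    spatial <- utils::modifyList(
      list(rank = min(50L, n), range_h = NULL, scale = 0.5), spatial)
  }
  if (!is.null(groups)) {
    groups <- utils::modifyList(list(n_groups = 10L, effect_sd = 0.5), groups)
  }
  structure(list(n = n, beta0 = beta0, beta = beta, sigma2 = sigma2,
                 spatial = spatial, groups = groups, offset = offset,
                 seed = as.integer(seed), n_iter = as.integer(n_iter)),
            class = "scenario_config")
}

#' Generate one scenario replication
#'
#' Draws covariates, optional spatial field and group effects, forms
#' `lambda_i = z_i exp(beta0 + x_i' beta + s_i + g_i)`, and samples counts
#' via [gen_odpoisson()]. Fully reproducible: iteration `j` of a scenario
#' always uses seed `config$seed + j`.
#'
#' @param config A [scenario_config()].
#' @param iteration Replication index (1-based).
#' @return A list with the [count_dataset()] in `$data` and a `$truth` record
#'   (true `beta` including intercept, `sigma2`, and spatial field `s` /
#'   group effects `g` when present).
#' @export
gen_scenario_dataset <- function(config, iteration = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  old <- local_seed(config$seed + as.integer(iteration))
  on.exit(restore_seed(old))
  n <- config$n
  k <- length(config$beta)
  X <- cbind(1, matrix(stats::rnorm(n * k), n, k))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k)))
  eta <- drop(X %*% c(config$beta0, config$beta))

  coords <- NULL; s <- NULL
  if (!is.null(config$spatial)) {
    coords <- cbind(stats::runif(n), stats::runif(n))
    basis <- build_lowrank_gp_basis(coords, rank = config$spatial$rank,
                                    range_h = config$spatial$range_h)
    s <- drop(basis$Z %*% stats::rnorm(ncol(basis$Z), sd = config$spatial$scale))
    eta <- eta + s
  }
  grp <- NULL; g_eff <- NULL
  if (!is.null(config$groups)) {
    ng <- config$groups$n_groups
    lab <- factor(sample.int(ng, n, replace = TRUE), levels = seq_len(ng))
    u <- stats::rnorm(ng, sd = config$groups$effect_sd)
    g_eff <- u[as.integer(lab)]
    eta <- eta + g_eff
    grp <- list(group = lab)
  }
  z <- if (is.function(config$offset)) config$offset(n) else rep(config$offset, n)
  lambda <- z * exp(eta)
  y <- gen_odpoisson(lambda, config$sigma2)
  list(data = count_dataset(y = y, X = X, z = z, groups = grp, coords = coords),
       truth = list(beta = setNames(c(config$beta0, config$beta), colnames(X)),
                    sigma2 = config$sigma2, s = s, g = g_eff,
                    group_u = if (!is.null(config$groups)) u else NULL,
                    lambda = lambda))
}

# RNG bookkeeping: set a local seed and restore the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
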