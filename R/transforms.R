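#' Share of zero counts
#'
#' The zero ratio `r = #\{y_i = 0\} / N` is the data summary that blends the
#' mode-based and mean-based log-Gaussian approximations: with no zeros the
#' transform centres on the Poisson mode, and as zeros dominate it shifts
#' towards matching the mean.
#'
#' @param y Non-negative integer counts.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' zero_ratio(c(0, 0, 1, 3)) # 0.5
zero_ratio <- function(y) {
  if (length(y) < 1L) stop("'y' must have length >= 1", call. = FALSE)
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  mean(y == 0)
}

#' Mode-matched log-Gaussian transform of a count response
#'
#' Computes the working response of the proposed approximation,
#' \deqn{\log(y_i^+) = \log\{(y_i + 0.5)/z_i\} - (1 + 0.5r)/(y_i + 0.5),}
#' with weights \eqn{y_i + 0.5}, where `r` is the zero ratio of the response.
#' `r = 0` gives the pure mode-matched transform (exponent 1), `r = 1` the
#' mean-rescaled transform (exponent 1.5); intermediate `r` blends the two.
#' The weight is the plug-in precision of the log-Gaussian working model,
#' so weighted least squares of `log_yplus` on the design matrix is the
#' first step of the two-step estimator.
#'
#' @param y Non-negative integer counts.
#' @param z Positive offsets (scalar or length of `y`).
#' @param r Zero ratio in `[0, 1]`; defaults to `zero_ratio(y)`.
#' @return A list of class `transformed_response` with `log_yplus`, `weights`,
#'   `r`, `method = "proposed"`, and `c = NA` (no tuning constant).
#' @export
#' @examples
#' tr <- proposed_transform(c(0, 1, 4))
#' tr$log_yplus
proposed_transform <- function(y, z = 1, r = zero_ratio(y)) {
  if (length(r) != 1L || is.na(r) || r < 0 || r > 1) {
    stop("'r' must be a single number in [0, 1]", call. = FALSE)
  }
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(z) == 1L) z <- rep(z, length(y))
  if (length(z) != length(y)) stop("'y' and 'z' lengths differ", call. = FALSE)
  if (any(z <= 0)) stop("offsets must be positive", call. = FALSE)
  w <- y + 0.5
  structure(
    list(log_yplus = log(w / z) - (1 + 0.5 * r) / w,
         weights = w, r = r, method = "proposed", c = NA_real_),
    class = "transformed_response"
  )
}

#' Comparator log-Gaussian transforms (log-linear and Taylor)
#'
#' The classical closed-form Gaussian approximations that require a tuning
#' constant `c > 0` chosen a priori: the log-linear transform
#' `log(y_i + c)` and the Taylor (log-Gamma) transform
#' `log(y_i + c) - c/(y_i + c)`, both with weights `y_i + c`. Offsets enter by
#' subtracting `log(z_i)`, mirroring the proposed transform, so all methods
#' accept offsets uniformly.
#'
#' @param y Non-negative integer counts.
#' @param c Positive tuning constant; default 0.5.
#' @param method `"loglinear"` or `"taylor"`.
#' @param z Positive offsets (scalar or length of `y`).
#' @return A `transformed_response` list (see [proposed_transform()]).
#' @export
comparator_transform <- function(y, c = 0.5, method = c("loglinear", "taylor"),
                                 z = 1) {
  method <- match.arg(method)
  if (length(c) != 1L || is.na(c) || c <= 0) {
    stop("'c' must be a single positive number", call. = FALSE)
  }
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(z) == 1L) z <- rep(z, length(y))
  if (any(z <= 0)) stop("offsets must be positive", call. = FALSE)
  w <- y + c
  ly <- log(w) - log(z)
  if (method == "taylor") ly <- ly - c / w
  structure(
    list(log_yplus = ly, weights = w, r = zero_ratio(y), method = method, c = c),
    class = "transformed_response"
  )
}

#' Solve for the mode-matching constant
#'
#' Mode matching between the Poisson model (mode centre `lambda - 0.5`) and
#' the approximating log-Gaussian model `y + c ~ LogN(mu_G, 1/(lambda + c))`
#' imposes
#' \deqn{z e^{\mu} - 0.5 = \exp\{\mu_G - 1/(\lambda + c)\} - c.}
#' Only one value of `c` makes the induced location
#' \eqn{\mu_G(\mu) = 1/(\lambda + c) + \log(z e^\mu - 0.5 + c)} an affine,
#' unit-slope function of `mu` for every `lambda`; this routine recovers that
#' constant numerically by minimising, over a grid of `mu` (with `z = 1`),
#' the spread of \eqn{\mu_G - 1/(\lambda + c) - \mu}. It is a verification
#' utility (a test oracle): the constant is mathematical, not a runtime
#' parameter, and nothing on the fitting path calls this function.
#'
#' @param mu_grid Grid of linear-predictor values; kept above `log(0.5)` so
#'   the mode centre is non-negative.
#' @param interval Search interval for `c`.
#' @param tol Convergence tolerance passed to [stats::optimize()].
#' @return The mode-matching constant (numerically ~0.5), with attributes
#'   `residual` (the attained nonlinearity, ~0) and `n_grid`.
#' @export
solve_mode_matching_constant <- function(mu_grid = seq(log(0.6), 3, length.out = 201),
                                         interval = c(0.05, 1.5),
                                         tol = 1e-12) {
  nonlinearity <- function(cc) {
    lam <- exp(mu_grid) # z = 1
    arg <- lam - 0.5 + cc
    if (any(arg <= 0)) return(Inf)
    mu_g <- 1 / (lam + cc) + log(arg)
    stats::sd(mu_g - 1 / (lam + cc) - mu_grid)
  }
  opt <- stats::optimize(nonlinearity, interval = interval, tol = tol)
  structure(opt$minimum, residual = opt$objective, n_grid = length(mu_grid))
}
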