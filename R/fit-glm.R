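# Fixed-effects estimators: IRLS Poisson / over-dispersed Poisson, the
# two-step mode-matched plug-in estimator, weighted-Gaussian comparator fits,
# and negative binomial regression.

LAMBDA_FLOOR <- 1e-10 # floor for fitted means in divisions
BETA_BOUND <- 30      # |beta_k| beyond this declares divergence (identification failure)

new_fixed_fit <- function(beta, cov_beta, sigma2, lambda_hat, mu_hat, method,
                          converged = TRUE, n_iter = 0L, extra = NULL) {
  names(beta) <- rownames(cov_beta) <- colnames(cov_beta) <- names(beta)
  out <- c(list(beta = beta, cov_beta = cov_beta, sigma2 = sigma2,
                lambda_hat = lambda_hat, mu_hat = mu_hat, method = method,
                converged = converged, n_iter = n_iter), extra)
  class(out) <- "fixed_fit"
  out
}

#' @export
print.fixed_fit <- function(x, ...) {
  cat(sprintf("%s fit%s (%d obs)\n", x$method,
              if (x$converged) "" else " [NOT CONVERGED]",
              length(x$lambda_hat)))
  se <- sqrt(diag(x$cov_beta))
  tab <- cbind(Estimate = x$beta, `Std. Error` = se,
               `t value` = x$beta / se)
  print(round(tab, 4))
  cat(sprintf("Dispersion sigma^2 = %.4f\n", x$sigma2))
  invisible(x)
}

#' Coefficient summary of a fit
#'
#' @param object A `fixed_fit` or `mixed_fit`.
#' @param ... Unused.
#' @return A data frame with estimates, standard errors, and t values.
#' @export
coef_table <- function(object, ...) {
  se <- sqrt(pmax(diag(object$cov_beta), 0))
  data.frame(term = names(object$beta), estimate = unname(object$beta),
             std_error = se, t_value = unname(object$beta) / se,
             row.names = NULL)
}

# Dispersion estimator: sigma^2 = sum((y - lambda)^2 / lambda) / (N - df)
dispersion_estimate <- function(y, lambda, df) {
  lambda <- pmax(lambda, LAMBDA_FLOOR)
  sum((y - lambda)^2 / lambda) / (length(y) - df)
}

# Weighted least squares via the QR of sqrt(w) X; returns coefficients and
# the unscaled inverse crossproduct (X'WX)^{-1}.
wls_solve <- function(X, w, yresp) {
  sw <- sqrt(w)
  qrX <- qr(X * sw)
  if (qrX$rank < ncol(X)) {
    stop("weighted design is rank-deficient", call. = FALSE)
  }
  beta <- qr.coef(qrX, yresp * sw)
  R <- qr.R(qrX)
  xtwx_inv <- chol2inv(R[seq_len(ncol(X)), , drop = FALSE])
  dimnames(xtwx_inv) <- list(colnames(X), colnames(X))
  list(beta = beta, xtwx_inv = xtwx_inv)
}

#' Poisson / over-dispersed Poisson regression by IRLS
#'
#' Maximises the Poisson likelihood by iteratively re-weighted least squares:
#' given current means `lambda_i`, the working response
#' `mu_i + (y_i - lambda_i)/lambda_i` is regressed on `X` with weights
#' `lambda_i` until the coefficients stabilise. The point estimates are the
#' same whether or not over-dispersion is assumed; the over-dispersed variant
#' additionally estimates `sigma^2` by the moment estimator
#' `sum((y - lambda)^2/lambda)/(N - K)` and scales the coefficient covariance
#' by it.
#'
#' For small samples with many zeros the Poisson likelihood can be flat or
#' unbounded in directions of the coefficient space (the identification
#' problem); this shows up as coefficients drifting beyond `±30`, which is
#' reported as a divergence error rather than a hang.
#'
#' @param data A [count_dataset()].
#' @param overdispersed If `TRUE`, estimate `sigma^2` and scale the
#'   covariance; otherwise `sigma^2 = 1`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   `max |delta beta|`.
#' @return A `fixed_fit`.
#' @export
#' @examples
#' d <- count_dataset(y = c(0, 4))
#' fit_irls_poisson(d, overdispersed = TRUE)$sigma2 # 4
fit_irls_poisson <- function(data, overdispersed = FALSE,
                             max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(data, "count_dataset"))
  y <- data$y; z <- data$z; X <- data$X
  n <- data$n; k <- ncol(X)
  if (n <= k) stop("need more observations than coefficients", call. = FALSE)

  mu <- log((y + 0.5) / z) # initialisation
  beta <- wls_solve(X, rep(1, n), mu)$beta
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- drop(X %*% beta)
    lambda <- pmax(z * exp(mu), LAMBDA_FLOOR)
    wresp <- mu + (y - lambda) / lambda
    sol <- wls_solve(X, lambda, wresp)
    delta <- max(abs(sol$beta - beta))
    beta <- sol$beta
    if (any(abs(beta) > BETA_BOUND)) {
      stop(structure(
        class = c("lgpois_divergence_error", "error", "condition"),
        list(message = sprintf(
          "IRLS diverged at iteration %d: |beta| exceeded %g (identification problem)",
          it, BETA_BOUND), call = NULL, beta = beta)))
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(structure(
      class = c("lgpois_convergence_error", "error", "condition"),
      list(message = sprintf("IRLS did not converge in %d iterations", max_iter),
           call = NULL, beta = beta)))
  }
  mu <- drop(X %*% beta)
  lambda <- z * exp(mu)
  sol <- wls_solve(X, pmax(lambda, LAMBDA_FLOOR), mu)
  sigma2 <- if (overdispersed) dispersion_estimate(y, lambda, k) else 1
  new_fixed_fit(beta = setNames(beta, colnames(X)),
                cov_beta = sigma2 * sol$xtwx_inv,
                sigma2 = sigma2, lambda_hat = lambda, mu_hat = mu,
                method = if (overdispersed) "odpoisson" else "poisson",
                converged = TRUE, n_iter = it)
}

#' Two-step mode-matched plug-in estimator
#'
#' Step I regresses the mode-matched working response
#' `log(y+) = log((y + 0.5)/z) - (1 + 0.5 r)/(y + 0.5)` on `X` by weighted
#' least squares with weights `y + 0.5`, giving an identification-free
#' estimate `lambda+ = z exp(X beta+)` of the Poisson mean. Step II
#' substitutes `lambda+` into the IRLS normal equations exactly once: the
#' working response `mu+ + (y - lambda+)/lambda+` is regressed on `X` with
#' weights `lambda+`, yielding the final coefficients, the dispersion
#' `sigma^2 = sum((y - lambda+)^2/lambda+)/(N - K)`, and covariance
#' `sigma^2 (X' Lambda+ X)^{-1}`. No iteration occurs, so the estimator
#' cannot diverge.
#'
#' @inheritParams fit_irls_poisson
#' @return A `fixed_fit` with extra fields `beta_step1`, `lambda_plus`, `r`.
#' @export
fit_proposed <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  y <- data$y; z <- data$z; X <- data$X
  n <- data$n; k <- ncol(X)
  if (n <= k) stop("need more observations than coefficients", call. = FALSE)

  tr <- proposed_transform(y, z)
  s1 <- wls_solve(X, tr$weights, tr$log_yplus)
  mu_plus <- drop(X %*% s1$beta)
  lambda_plus <- pmax(z * exp(mu_plus), LAMBDA_FLOOR)

  wresp <- mu_plus + (y - lambda_plus) / lambda_plus
  s2 <- wls_solve(X, lambda_plus, wresp)
  beta <- setNames(s2$beta, colnames(X))
  sigma2 <- dispersion_estimate(y, lambda_plus, k)
  mu <- drop(X %*% beta)
  new_fixed_fit(beta = beta, cov_beta = sigma2 * s2$xtwx_inv, sigma2 = sigma2,
                lambda_hat = z * exp(mu), mu_hat = mu, method = "proposed",
                converged = TRUE, n_iter = 0L,
                extra = list(beta_step1 = setNames(s1$beta, colnames(X)),
                             lambda_plus = lambda_plus, r = tr$r))
}

#' Log-linear / Taylor weighted-Gaussian comparator fits
#'
#' Fits the classical single-stage Gaussian approximations: weighted least
#' squares of the comparator transform (see [comparator_transform()]) on `X`
#' with weights `y + c`. Coefficients and covariance come directly from the
#' Gaussian model; `sigma2` is the weighted residual variance.
#'
#' @inheritParams fit_irls_poisson
#' @param method `"loglinear"` or `"taylor"`.
#' @param c Positive tuning constant (must be chosen a priori); default 0.5.
#' @return A `fixed_fit`.
#' @export
fit_comparator <- function(data, method = c("loglinear", "taylor"), c = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(data, "count_dataset"))
  y <- data$y; z <- data$z; X <- data$X
  n <- data$n; k <- ncol(X)
  if (n <= k) stop("need more observations than coefficients", call. = FALSE)

  tr <- comparator_transform(y, c = c, method = method, z = z)
  sol <- wls_solve(X, tr$weights, tr$log_yplus)
  beta <- setNames(sol$beta, colnames(X))
  mu <- drop(X %*% beta)
  resid <- tr$log_yplus - mu
  sigma2 <- sum(tr$weights * resid^2) / (n - k)
  new_fixed_fit(beta = beta, cov_beta = sigma2 * sol$xtwx_inv, sigma2 = sigma2,
                lambda_hat = z * exp(mu), mu_hat = mu, method = method,
                converged = TRUE, n_iter = 0L, extra = list(c = c))
}

#' Negative binomial (NB2) regression
#'
#' Maximum-likelihood NB2 fit with mean `lambda_i = z_i exp(x_i' beta)` and
#' variance `lambda_i + alpha lambda_i^2`, delegating to [MASS::glm.nb()].
#' `sigma2` is reported as the implied dispersion at the mean fitted value,
#' `1 + alpha * mean(lambda_hat)`. When the data are effectively Poisson the
#' size parameter runs to its boundary; this is reported as
#' Poisson-equivalent (`alpha ~ 0`), not an error.
#'
#' @inheritParams fit_irls_poisson
#' @return A `fixed_fit` with extra field `alpha` (NB2 dispersion).
#' @export
fit_negbin <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  y <- data$y; z <- data$z; X <- data$X
  if (data$n <= ncol(X)) stop("need more observations than coefficients", call. = FALSE)

  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  df$.y <- y
  form <- stats::as.formula(paste(".y ~ 0 + offset(log(z)) +",
                                  paste(names(df)[seq_len(ncol(X))], collapse = " + ")))
  fit <- suppressWarnings(tryCatch(
    MASS::glm.nb(form, data = df, link = "log"),
    error = function(e) {
      stop(structure(
        class = c("lgpois_convergence_error", "error", "condition"),
        list(message = paste("NB2 fit failed:", conditionMessage(e)), call = NULL)))
    }))
  beta <- setNames(unname(stats::coef(fit)), colnames(X))
  lambda <- unname(stats::fitted(fit))
  alpha <- 1 / fit$theta
  cov_beta <- unname(stats::vcov(fit))
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  new_fixed_fit(beta = beta, cov_beta = cov_beta,
                sigma2 = 1 + alpha * mean(lambda),
                lambda_hat = lambda, mu_hat = log(lambda / z),
                method = "negbin", converged = fit$converged,
                n_iter = fit$iter, extra = list(alpha = alpha))
}

#' Fit a fixed-effects count regression by any supported method
#'
#' Convenience dispatcher over the estimators in the package.
#'
#' @inheritParams fit_irls_poisson
#' @param method One of `"poisson"`, `"odpoisson"`, `"negbin"`,
#'   `"loglinear"`, `"taylor"`, `"proposed"`.
#' @param c Tuning constant for the comparator transforms.
#' @param ... Passed to the underlying fitter.
#' @return A `fixed_fit`.
#' @export
fit_count_glm <- function(data, method = c("proposed", "poisson", "odpoisson",
                                           "negbin", "loglinear", "taylor"),
                          c = 0.5, ...) {
  method <- match.arg(method)
  switch(method,
    poisson = fit_irls_poisson(data, overdispersed = FALSE, ...),
    odpoisson = fit_irls_poisson(data, overdispersed = TRUE, ...),
    negbin = fit_negbin(data),
    loglinear = fit_comparator(data, method = "loglinear", c = c),
    taylor = fit_comparator(data, method = "taylor", c = c),
    proposed = fit_proposed(data))
}
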