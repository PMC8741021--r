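# Mixed-effects / additive extension: random-effect design builders, a
# profile-REML engine for the weighted Gaussian working model, and the
# two-step plug-in estimators for the over-dispersed Poisson MEM.

#' Random-intercept design block from group labels
#'
#' @param labels Categorical vector with at least two distinct levels.
#' @param name Block label.
#' @return A random-effect block: list with indicator matrix `Z` (one column
#'   per level, exactly one 1 per row), `label`, and `type = "group"`. The
#'   implied prior on the block coefficients is `tau^2 I` with `tau^2`
#'   estimated by REML.
#' @export
build_group_design <- function(labels, name = "group") {
  f <- as.factor(labels)
  if (nlevels(f) < 2L) {
    stop("group effect needs at least 2 distinct levels", call. = FALSE)
  }
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  colnames(Z) <- paste0(name, ".", levels(f))
  list(Z = Z, label = name, type = "group")
}

#' Low-rank Gaussian-process basis from planar coordinates
#'
#' Builds the exponential-kernel matrix `C_ij = exp(-d_ij / h)` on Euclidean
#' distances, eigendecomposes it, and returns the scaled eigenbasis
#' `E_m diag(sqrt(ev_m))` of the top `m` eigenpairs. With an iid `tau^2`
#' prior on the basis coefficients the implied process covariance is
#' `tau^2` times the rank-`m` truncation of `C`, the standard
#' predictive-process / low-rank GP construction for spatial random effects.
#'
#' @param coords N x 2 matrix of planar coordinates.
#' @param rank Number of eigenpairs retained; default `min(50, N)`.
#' @param range_h Kernel range (same units as the coordinates); default the
#'   median inter-point distance.
#' @param name Block label.
#' @return A random-effect block: list with basis matrix `Z` (N x rank),
#'   `label`, `type = "gp"`, plus `eigenvalues`, `range_h`.
#' @export
build_lowrank_gp_basis <- function(coords, rank = NULL, range_h = NULL,
                                   name = "gp") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("'coords' must be N x 2", call. = FALSE)
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("'coords' contains non-finite values", call. = FALSE)
  }
  n <- nrow(coords)
  if (is.null(rank)) rank <- min(50L, n)
  if (rank > n) stop("'rank' cannot exceed the number of points", call. = FALSE)
  if (rank < 1L) stop("'rank' must be >= 1", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  if (is.null(range_h)) {
    range_h <- stats::median(d[upper.tri(d)])
    if (!is.finite(range_h) || range_h <= 0) range_h <- 1
  }
  if (range_h <= 0) stop("'range_h' must be positive", call. = FALSE)
  C <- exp(-d / range_h)
  eg <- eigen(C, symmetric = TRUE)
  keep <- seq_len(rank)
  ev <- pmax(eg$values[keep], 0)
  Z <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev), rank)
  colnames(Z) <- paste0(name, ".", keep)
  list(Z = Z, label = name, type = "gp", eigenvalues = ev, range_h = range_h)
}

# Assemble random-effect blocks (a single block or a list of blocks) into a
# combined matrix plus an index of which columns belong to which block.
assemble_redesign <- function(redesign) {
  if (is.null(redesign) || length(redesign) == 0L) {
    return(list(Z = NULL, blocks = list(), index = list()))
  }
  if (!is.null(redesign$Z)) redesign <- list(redesign)
  Zs <- lapply(redesign, `[[`, "Z")
  Z <- do.call(cbind, Zs)
  if (any(colSums(abs(Z)) == 0)) {
    stop("random-effect design has an all-zero column", call. = FALSE)
  }
  sizes <- vapply(Zs, ncol, 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  index <- Map(seq, starts, ends)
  names(index) <- vapply(redesign, `[[`, "", "label")
  list(Z = Z, blocks = redesign, index = index)
}

#' Weighted Gaussian mixed model by profile REML
#'
#' Fits `y = X b + sum_l Z_l u_l + e` with `u_l ~ N(0, tau_l^2 I)` and
#' `e_i ~ N(0, phi / w_i)` for known weights `w`. The variance ratios
#' `gamma_l = tau_l^2 / phi` are estimated by maximising the restricted
#' likelihood (the noise scale `phi` is profiled out in closed form); the
#' coefficients at the optimum are the penalized weighted-least-squares
#' solution
#' `(X~' W X~ + P)^{-1} X~' W y` with `X~ = [X, Z]` and block penalty
#' `P = diag(0, gamma_l^{-1} I)`, i.e. the usual BLUP. The effective degrees
#' of freedom is the trace `tr[(X~' W X~ + P)^{-1} X~' W X~]` over the full
#' column set.
#'
#' Variance ratios are optimised on the log scale with a small lower bound so
#' the penalty stays finite; a ratio at the bound is reported, not errored.
#' With `method = "ML"` the unrestricted likelihood is maximised instead.
#'
#' @param response Numeric response vector.
#' @param weights Positive known weights (inverse relative variances).
#' @param X Fixed-effects design matrix.
#' @param redesign A random-effect block (from [build_group_design()] or
#'   [build_lowrank_gp_basis()]), a list of blocks, or `NULL` for plain WLS.
#' @param method `"REML"` (default) or `"ML"`.
#' @param fixed_gamma Optional fixed variance ratios (recycled over blocks),
#'   bypassing optimisation; `Inf` means unpenalized.
#' @return A list with `beta` (fixed + random coefficients), `tau2` (per
#'   block), `phi` (noise scale), `gamma`, `edof`, `fitted`, `penalty`
#'   (diagonal of `P`), `cov_unscaled` (`(X~'WX~ + P)^{-1}`), `Xtilde`,
#'   `index` (column indices per block), and `converged`.
#' @export
fit_gaussian_mem_reml <- function(response, weights, X, redesign = NULL,
                                  method = c("REML", "ML"),
                                  fixed_gamma = NULL) {
  method <- match.arg(method)
  y <- as.numeric(response)
  w <- as.numeric(weights)
  n <- length(y)
  stopifnot(length(w) == n, nrow(X) == n, all(w > 0))
  asm <- assemble_redesign(redesign)
  Z <- asm$Z
  p <- ncol(X)
  nblk <- length(asm$index)

  if (nblk == 0L) {
    sol <- wls_solve(X, w, y)
    fitted <- drop(X %*% sol$beta)
    phi <- sum(w * (y - fitted)^2) / (n - p)
    return(list(beta = setNames(sol$beta, colnames(X)), tau2 = numeric(0),
                phi = phi, gamma = numeric(0), edof = p, fitted = fitted,
                penalty = rep(0, p), cov_unscaled = sol$xtwx_inv,
                Xtilde = X, index = list(), converged = TRUE))
  }

  Zs <- lapply(asm$index, function(ix) Z[, ix, drop = FALSE])
  crit <- function(log_gamma) {
    g <- exp(log_gamma)
    V0 <- diag(1 / w, n)
    for (l in seq_len(nblk)) V0 <- V0 + g[l] * tcrossprod(Zs[[l]])
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(1e10)
    b <- backsolve(chX, forwardsolve(t(chX), crossprod(X, Vi_y)))
    r <- y - drop(X %*% b)
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    quad <- sum(r * Vi_r)
    if (quad <= 0) return(1e10)
    if (method == "REML") {
      0.5 * (logdetV + 2 * sum(log(diag(chX))) + (n - p) * log(quad))
    } else {
      0.5 * (logdetV + n * log(quad))
    }
  }

  converged <- TRUE
  if (!is.null(fixed_gamma)) {
    gamma <- rep_len(fixed_gamma, nblk)
  } else {
    lower <- log(1e-10); upper <- log(1e8)
    if (nblk == 1L) {
      opt <- stats::optimize(crit, interval = c(lower, upper), tol = 1e-8)
      gamma <- exp(opt$minimum)
    } else {
      opt <- stats::optim(rep(0, nblk), crit, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 200))
      if (opt$convergence != 0) converged <- FALSE
      gamma <- exp(opt$par)
    }
  }

  Xt <- cbind(X, Z)
  q <- ncol(Xt)
  pen <- c(rep(0, p), unlist(Map(function(ix, g) rep(1 / g, length(ix)),
                                 asm$index, gamma), use.names = FALSE))
  A <- crossprod(Xt * sqrt(w)) # X~' W X~
  Ap <- A + diag(pen, q)
  chA <- chol(Ap)
  cov_unscaled <- chol2inv(chA)
  beta <- drop(cov_unscaled %*% crossprod(Xt, w * y))
  names(beta) <- colnames(Xt)
  fitted <- drop(Xt %*% beta)
  edof <- sum(diag(cov_unscaled %*% A))
  df_resid <- max(n - edof, 1)
  phi <- sum(w * (y - fitted)^2) / df_resid
  tau2 <- gamma * phi
  names(tau2) <- names(gamma) <- names(asm$index)
  index_xt <- lapply(asm$index, `+`, p) # block columns within [X, Z]
  list(beta = beta, tau2 = tau2, phi = phi, gamma = gamma, edof = edof,
       fitted = fitted, penalty = pen, cov_unscaled = cov_unscaled,
       Xtilde = Xt, index = index_xt, converged = converged)
}

new_mixed_fit <- function(gfit, beta, cov_beta, sigma2, lambda_hat, mu_hat,
                          method, converged = TRUE, n_iter = 0L, extra = NULL) {
  p <- ncol(gfit$Xtilde) - length(unlist(gfit$index))
  ranef <- lapply(gfit$index, function(ix) beta[ix])
  out <- c(list(beta = beta, cov_beta = cov_beta, sigma2 = sigma2,
                tau2 = gfit$tau2, edof = gfit$edof,
                lambda_hat = lambda_hat, mu_hat = mu_hat,
                random_effects = lapply(gfit$index, function(ix) {
                  drop(gfit$Xtilde[, ix, drop = FALSE] %*% beta[ix])
                }),
                ranef_coef = ranef, n_fixed = p,
                method = method, converged = converged, n_iter = n_iter),
          extra)
  class(out) <- c("mixed_fit", "fixed_fit")
  out
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("%s mixed-model fit%s (%d obs, edof = %.2f)\n", x$method,
              if (x$converged) "" else " [NOT CONVERGED]",
              length(x$lambda_hat), x$edof))
  ix <- seq_len(x$n_fixed)
  se <- sqrt(pmax(diag(x$cov_beta)[ix], 0))
  tab <- cbind(Estimate = x$beta[ix], `Std. Error` = se,
               `t value` = x$beta[ix] / se)
  print(round(tab, 4))
  cat(sprintf("Dispersion sigma^2 = %.4f; variance components tau^2: %s\n",
              x$sigma2, paste(sprintf("%s = %.4g", names(x$tau2), x$tau2),
                              collapse = ", ")))
  invisible(x)
}

#' Two-step mode-matched estimator for the over-dispersed Poisson MEM
#'
#' Step I fits the Gaussian mixed model to the mode-matched working response
#' `log(y+)` with weights `y + 0.5` by REML ([fit_gaussian_mem_reml()]),
#' giving `mu+ = X~ beta+`, `lambda+ = z exp(mu+)`, and the estimated block
#' penalties. Step II evaluates the penalized IRLS normal equations exactly
#' once at `lambda+`: with working response `z+ = mu+ + (y - lambda+)/lambda+`,
#' \deqn{\hat\beta = (X~' \Lambda^+ X~ + P)^{-1} X~' \Lambda^+ z^+,}
#' covariance `sigma^2 (X~' Lambda+ X~ + P)^{-1}`, and dispersion
#' `sigma^2 = sum((y - lambda+)^2/lambda+)/(N - L)` with `L` the effective
#' degrees of freedom trace at `Lambda+`. The penalty `P` estimated in step I
#' is reused without re-estimation. With no random blocks this reduces
#' exactly to [fit_proposed()].
#'
#' @param data A [count_dataset()].
#' @param redesign Random-effect block(s); `NULL` reduces to the
#'   fixed-effects two-step fit.
#' @param method Variance-component criterion, `"REML"` or `"ML"`.
#' @return A `mixed_fit`.
#' @export
fit_mem_proposed <- function(data, redesign = NULL, method = "REML") {
  stopifnot(inherits(data, "count_dataset"))
  y <- data$y; z <- data$z
  tr <- proposed_transform(y, z)
  g <- fit_gaussian_mem_reml(tr$log_yplus, tr$weights, data$X, redesign,
                             method = method)
  Xt <- g$Xtilde
  mu_plus <- g$fitted
  lambda_plus <- pmax(z * exp(mu_plus), LAMBDA_FLOOR)

  wresp <- mu_plus + (y - lambda_plus) / lambda_plus
  A <- crossprod(Xt * sqrt(lambda_plus))
  Ap <- A + diag(g$penalty, ncol(Xt))
  cov_unscaled <- chol2inv(chol(Ap))
  beta <- drop(cov_unscaled %*% crossprod(Xt, lambda_plus * wresp))
  names(beta) <- colnames(Xt)
  L <- sum(diag(cov_unscaled %*% A))
  sigma2 <- sum((y - lambda_plus)^2 / lambda_plus) / (length(y) - L)
  mu <- drop(Xt %*% beta)
  gfit <- g; gfit$edof <- L
  new_mixed_fit(gfit, beta = beta, cov_beta = sigma2 * cov_unscaled,
                sigma2 = sigma2, lambda_hat = z * exp(mu), mu_hat = mu,
                method = "proposed", converged = TRUE, n_iter = 0L,
                extra = list(beta_step1 = g$beta, lambda_plus = lambda_plus,
                             r = tr$r, phi_step1 = g$phi))
}

#' Comparator estimators for the Poisson MEM
#'
#' `"poisson"` and `"odpoisson"` fit the (over-dispersed) Poisson mixed model
#' by penalized quasi-likelihood: the IRLS working response is re-fitted as a
#' weighted Gaussian mixed model (variance components by REML on the working
#' model) until the coefficients stabilise. `"taylor"` fits the Gaussian
#' mixed model to the Taylor transform with its `y + c` weights, a
#' single-stage approximation. For small over-dispersed samples with many
#' zeros the penalized IRLS can diverge — the same identification problem as
#' the fixed-effects Poisson MLE — and then a divergence error is raised.
#'
#' @inheritParams fit_mem_proposed
#' @param method `"poisson"`, `"odpoisson"`, or `"taylor"`.
#' @param c Tuning constant for the Taylor transform.
#' @param max_iter,tol PQL iteration cap and tolerance on `max |delta beta|`.
#' @param reml Variance-component criterion for the inner Gaussian fits.
#' @return A `mixed_fit`.
#' @export
fit_mem_comparator <- function(data, redesign = NULL,
                               method = c("poisson", "odpoisson", "taylor"),
                               c = 0.5, max_iter = 50L, tol = 1e-6,
                               reml = "REML") {
  method <- match.arg(method)
  stopifnot(inherits(data, "count_dataset"))
  y <- data$y; z <- data$z; X <- data$X
  n <- data$n

  if (method == "taylor") {
    tr <- comparator_transform(y, c = c, method = "taylor", z = z)
    g <- fit_gaussian_mem_reml(tr$log_yplus, tr$weights, X, redesign,
                               method = reml)
    mu <- g$fitted
    return(new_mixed_fit(g, beta = g$beta, cov_beta = g$phi * g$cov_unscaled,
                         sigma2 = g$phi, lambda_hat = z * exp(mu), mu_hat = mu,
                         method = "taylor", converged = g$converged,
                         n_iter = 0L, extra = list(c = c)))
  }

  # PQL: penalized IRLS with REML variance components on the working model
  mu <- log((y + 0.5) / z)
  beta <- NULL
  g <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lambda <- pmax(z * exp(mu), LAMBDA_FLOOR)
    wresp <- mu + (y - lambda) / lambda
    g <- fit_gaussian_mem_reml(wresp, lambda, X, redesign, method = reml)
    delta <- if (is.null(beta)) Inf else max(abs(g$beta - beta))
    beta <- g$beta
    if (any(abs(beta[seq_len(ncol(X))]) > BETA_BOUND)) {
      stop(structure(
        class = c("lgpois_divergence_error", "error", "condition"),
        list(message = sprintf(
          "penalized IRLS diverged at iteration %d: |beta| exceeded %g",
          it, BETA_BOUND), call = NULL, beta = beta)))
    }
    mu <- g$fitted
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(structure(
      class = c("lgpois_convergence_error", "error", "condition"),
      list(message = sprintf("penalized IRLS did not converge in %d iterations",
                             max_iter), call = NULL, beta = beta)))
  }
  lambda <- pmax(z * exp(mu), LAMBDA_FLOOR)
  Xt <- g$Xtilde
  A <- crossprod(Xt * sqrt(lambda))
  cov_unscaled <- chol2inv(chol(A + diag(g$penalty, ncol(Xt))))
  L <- sum(diag(cov_unscaled %*% A))
  sigma2 <- if (method == "odpoisson") {
    sum((y - lambda)^2 / lambda) / (n - L)
  } else 1
  gfit <- g; gfit$edof <- L
  new_mixed_fit(gfit, beta = beta, cov_beta = sigma2 * cov_unscaled,
                sigma2 = sigma2, lambda_hat = lambda, mu_hat = mu,
                method = method, converged = TRUE, n_iter = it)
}
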