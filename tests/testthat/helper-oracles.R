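# Independent oracles used across test files. These deliberately avoid the
# package's own linear-algebra paths: weighted least squares is solved by
# explicit normal equations, and the Poisson likelihood is maximised by a
# coarse grid search refined with Nelder-Mead on the log-likelihood.

# Normal-equations WLS: (X'WX)^{-1} X'W y via solve().
oracle_wls <- function(X, w, y) {
  XtW <- t(X * w)
  unname(drop(solve(XtW %*% X, XtW %*% y)))
}

# Penalized WLS: (X'WX + P)^{-1} X'W y with P a diagonal penalty vector.
oracle_penalized_wls <- function(X, w, y, pen) {
  XtW <- t(X * w)
  unname(drop(solve(XtW %*% X + diag(pen, ncol(X)), XtW %*% y)))
}

# Poisson log-likelihood (up to a constant) for counts y, offsets z.
oracle_pois_loglik <- function(beta, X, y, z) {
  eta <- drop(X %*% beta)
  sum(y * (log(z) + eta) - z * exp(eta))
}

# Maximise the Poisson likelihood independently of IRLS: locate the best
# cell on a coarse grid over [-3, 3]^2, then polish with Nelder-Mead.
oracle_pois_mle_2d <- function(X, y, z = rep(1, length(y))) {
  grid <- seq(-3, 3, by = 0.1)
  best <- c(0, 0); best_ll <- -Inf
  for (b1 in grid) for (b2 in grid) {
    ll <- oracle_pois_loglik(c(b1, b2), X, y, z)
    if (ll > best_ll) { best_ll <- ll; best <- c(b1, b2) }
  }
  opt <- stats::optim(best, function(b) -oracle_pois_loglik(b, X, y, z),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$par
}

# A small random Poisson-regression dataset.
make_random_dataset <- function(n = 30, beta = c(0.3, 0.6), seed = 1,
                                sigma2 = 1, zmax = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (length(beta) - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  z <- if (zmax > 1) runif(n, 1, zmax) else rep(1, n)
  lambda <- z * exp(drop(X %*% beta))
  y <- lgpois::gen_odpoisson(lambda, sigma2)
  lgpois::count_dataset(y = y, X = X, z = z)
}
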