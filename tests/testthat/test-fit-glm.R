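test_that("count_dataset validates its invariants", {
  expect_error(count_dataset(c(-1, 2)), "non-negative")
  expect_error(count_dataset(c(1.5, 2)), "non-negative integers")
  expect_error(count_dataset(c(1, 2), z = c(1, 0)), "positive")
  expect_error(count_dataset(c(1, 2, 3), X = cbind(1, c(2, 2, 2))),
               "rank-deficient")
  d <- count_dataset(c(0, 2, 5), X = cbind(1, c(-1, 0, 1)), z = 2)
  expect_equal(d$n, 3)
  expect_equal(d$z, rep(2, 3))
})

test_that("IRLS recovers closed-form intercept-only estimates", {
  f <- fit_irls_poisson(count_dataset(c(2, 2, 2)))
  expect_equal(unname(f$beta), log(2), tolerance = 1e-10)
  expect_equal(unname(f$lambda_hat), rep(2, 3), tolerance = 1e-10)
  expect_identical(f$sigma2, 1)

  f2 <- fit_irls_poisson(count_dataset(c(0, 4)), overdispersed = TRUE)
  expect_equal(unname(f2$lambda_hat), c(2, 2), tolerance = 1e-10)
  expect_equal(f2$sigma2, 4, tolerance = 1e-10)
})

test_that("IRLS agrees with an independent likelihood maximisation", {
  d <- make_random_dataset(n = 20, beta = c(0.4, 0.9), seed = 11)
  f <- fit_irls_poisson(d)
  oracle <- oracle_pois_mle_2d(d$X, d$y, d$z)
  expect_equal(unname(f$beta), oracle, tolerance = 1e-4)
  # and with stats::glm as a second, independent route
  g <- stats::glm(d$y ~ 0 + d$X, family = stats::poisson())
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-8)
})

test_that("over-dispersed and plain Poisson IRLS share point estimates", {
  for (s in 1:5) {
    d <- make_random_dataset(n = 40, beta = c(0.2, 0.7), seed = 100 + s,
                             sigma2 = 3)
    fp <- fit_irls_poisson(d, overdispersed = FALSE)
    fo <- fit_irls_poisson(d, overdispersed = TRUE)
    expect_identical(fp$beta, fo$beta)
    expect_identical(fp$lambda_hat, fo$lambda_hat)
    expect_equal(fo$cov_beta, fo$sigma2 * fp$cov_beta, tolerance = 1e-12)
  }
})

test_that("two-step estimator matches the hand-evaluated example", {
  f <- fit_proposed(count_dataset(c(2, 2, 2)))
  mu_plus <- log(2.5) - 1 / 2.5
  lam_plus <- exp(mu_plus)
  expect_equal(unname(f$beta_step1), mu_plus, tolerance = 1e-12)
  expect_equal(unname(f$lambda_plus), rep(lam_plus, 3), tolerance = 1e-12)
  expect_equal(unname(f$beta), mu_plus + (2 - lam_plus) / lam_plus,
               tolerance = 1e-12)
})

test_that("step-I WLS equals the normal-equations oracle", {
  for (s in 1:10) {
    d <- make_random_dataset(n = 25, beta = c(0.5, 0.8), seed = 200 + s)
    f <- fit_proposed(d)
    tr <- proposed_transform(d$y, d$z)
    expect_equal(unname(f$beta_step1),
                 oracle_wls(d$X, tr$weights, tr$log_yplus),
                 tolerance = 1e-10)
  }
})

test_that("two-step estimator approaches the Poisson MLE for large counts", {
  set.seed(42)
  X <- cbind(1, rnorm(300))
  lambda <- exp(drop(X %*% c(5.5, 0.2)))
  y <- rpois(300, lambda)
  stopifnot(all(y >= 50))
  d <- count_dataset(y, X = X)
  expect_equal(unname(fit_proposed(d)$beta),
               unname(fit_irls_poisson(d)$beta), tolerance = 0.02)
})

test_that("offset doubling shifts only the intercept by -log 2", {
  d <- make_random_dataset(n = 60, beta = c(1, 0.5), seed = 7)
  d2 <- count_dataset(d$y, X = d$X, z = 2 * d$z)
  for (fitter in list(fit_proposed, fit_irls_poisson,
                      function(x) fit_comparator(x, "taylor"))) {
    b1 <- fitter(d)$beta
    b2 <- fitter(d2)$beta
    expect_equal(unname(b2[1] - b1[1]), -log(2), tolerance = 1e-7)
    expect_equal(unname(b2[-1]), unname(b1[-1]), tolerance = 1e-7)
  }
})

test_that("comparator fits reproduce weighted-mean closed forms", {
  d <- count_dataset(c(2, 2, 2))
  expect_equal(unname(fit_comparator(d, "loglinear")$beta), log(2.5),
               tolerance = 1e-12)
  expect_equal(unname(fit_comparator(d, "taylor")$beta), log(2.5) - 0.5 / 2.5,
               tolerance = 1e-12)
  # equal weights: WLS equals OLS on the transformed response
  y <- c(3, 3, 3, 3)
  X <- cbind(1, c(-1, 0, 1, 2))
  dc <- count_dataset(y, X = X)
  f <- fit_comparator(dc, "loglinear")
  ols <- stats::lm.fit(X, comparator_transform(y, 0.5, "loglinear")$log_yplus)
  expect_equal(unname(f$beta), unname(ols$coefficients), tolerance = 1e-12)
})

test_that("the two-step fit never diverges on many-zero data where IRLS can", {
  set.seed(9)
  n_div <- 0L
  for (s in 1:25) {
    d <- make_random_dataset(n = 30, beta = c(-2.5, 2), seed = 300 + s,
                             sigma2 = 4)
    f <- fit_proposed(d) # must always return
    expect_true(f$converged)
    expect_true(all(is.finite(f$beta)))
    irls <- tryCatch(fit_irls_poisson(d), error = function(e) e)
    if (inherits(irls, "lgpois_divergence_error")) n_div <- n_div + 1L
  }
  # the identification-failure regime really is exercised
  expect_gt(n_div, 0L)
})

test_that("negative binomial fit recovers NB2 dispersion and its boundary", {
  set.seed(21)
  d <- count_dataset(gen_odpoisson(rep(5, 2000), sigma2 = 3.5, seed = 22))
  f <- fit_negbin(d)
  expect_equal(f$alpha, 0.5, tolerance = 0.1) # sigma2 = 1 + alpha*lambda
  expect_equal(unname(exp(f$beta)), mean(d$y), tolerance = 1e-6)

  # pure Poisson data: alpha near zero, coefficients near the Poisson MLE
  d0 <- make_random_dataset(n = 400, beta = c(1, 0.5), seed = 23)
  f0 <- fit_negbin(d0)
  expect_lt(f0$alpha, 0.05)
  expect_equal(unname(f0$beta), unname(fit_irls_poisson(d0)$beta),
               tolerance = 0.02)
})

test_that("divergence is reported as a typed error, not a hang", {
  # a dataset engineered for separation: the single positive count sits at
  # an extreme covariate value
  X <- cbind(1, c(rep(0, 10), 8))
  d <- count_dataset(c(rep(0, 10), 5), X = X)
  expect_error(fit_irls_poisson(d), class = "lgpois_divergence_error")
})
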