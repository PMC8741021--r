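test_that("group design builds one indicator column per level", {
  blk <- build_group_design(c("a", "a", "b"))
  expect_equal(unname(blk$Z), rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(unname(rowSums(blk$Z)), rep(1, 3))
  expect_equal(unname(colSums(blk$Z)), c(2, 1))
  expect_error(build_group_design(c("a", "a")), "2 distinct")
})

test_that("low-rank GP basis reproduces the 2-point eigenstructure", {
  coords <- rbind(c(0, 0), c(3, 4)) # distance 5
  h <- 2
  blk <- build_lowrank_gp_basis(coords, rank = 2, range_h = h)
  rho <- exp(-5 / h)
  expect_equal(sort(blk$eigenvalues), sort(c(1 + rho, 1 - rho)),
               tolerance = 1e-12)
  # full rank: B B' reproduces the kernel exactly
  expect_equal(tcrossprod(blk$Z), rbind(c(1, rho), c(rho, 1)),
               tolerance = 1e-12)
})

test_that("full-rank basis reproduces the kernel and coincident points match", {
  set.seed(5)
  coords <- cbind(runif(12), runif(12))
  coords[2, ] <- coords[1, ] # coincident pair
  blk <- build_lowrank_gp_basis(coords, rank = 12, range_h = 0.7)
  d <- as.matrix(dist(coords))
  expect_equal(tcrossprod(blk$Z), unname(exp(-d / 0.7)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(blk$Z[1, ], blk$Z[2, ], tolerance = 1e-8)
  expect_error(build_lowrank_gp_basis(coords, rank = 13), "exceed")
  expect_error(build_lowrank_gp_basis(coords * NA), "finite")
})

test_that("REML matches the balanced one-way ANOVA closed form", {
  set.seed(42)
  a <- 8; m <- 10
  g <- rep(seq_len(a), each = m)
  y <- 3 + rnorm(a, sd = sqrt(2))[g] + rnorm(a * m, sd = sqrt(1.5))
  fit <- fit_gaussian_mem_reml(y, rep(1, a * m), matrix(1, a * m, 1),
                               build_group_design(g))
  gm <- tapply(y, g, mean)
  MSE <- sum((y - gm[g])^2) / (a * (m - 1))
  MSA <- m * sum((gm - mean(gm))^2) / (a - 1)
  expect_equal(fit$phi, MSE, tolerance = 1e-6)
  expect_equal(unname(fit$tau2), (MSA - MSE) / m, tolerance = 1e-5)
  expect_equal(unname(fit$beta[1]), mean(gm), tolerance = 1e-8)
})

test_that("REML agrees with lme4 on an unbalanced weighted random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(43)
  n <- 70
  g <- sample(1:6, n, replace = TRUE)
  x <- rnorm(n)
  w <- runif(n, 0.5, 2)
  y <- 1 + 0.5 * x + rnorm(6, sd = 0.8)[g] + rnorm(n, sd = sqrt(1 / w))
  fit <- fit_gaussian_mem_reml(y, w, cbind(1, x), build_group_design(g))
  lf <- lme4::lmer(y ~ x + (1 | g), weights = w, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(fit$tau2), vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$phi, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$beta[1:2]), unname(lme4::fixef(lf)), tolerance = 1e-5)
})

test_that("zero-penalty limit gives plain WLS with full degrees of freedom", {
  set.seed(8)
  n <- 40
  X <- cbind(1, rnorm(n))
  blk <- build_lowrank_gp_basis(cbind(runif(n), runif(n)), rank = 5,
                                range_h = 0.5)
  w <- runif(n, 0.5, 2)
  y <- rnorm(n)
  fit <- fit_gaussian_mem_reml(y, w, X, blk, fixed_gamma = Inf)
  Xt <- cbind(X, blk$Z)
  expect_equal(unname(fit$beta), oracle_wls(Xt, w, y), tolerance = 1e-8)
  expect_equal(fit$edof, ncol(Xt), tolerance = 1e-8)
})

test_that("zero-residual data drives the variance components to zero", {
  set.seed(12)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) # exactly in the fixed-effect span
  blk <- build_lowrank_gp_basis(cbind(runif(n), runif(n)), rank = 4,
                                range_h = 0.5)
  fit <- fit_gaussian_mem_reml(y, rep(1, n), X, blk)
  expect_lt(unname(fit$tau2), 1e-6)
})

test_that("edof decreases with the penalty and is bounded by the column counts", {
  set.seed(13)
  n <- 50
  X <- cbind(1, rnorm(n))
  blk <- build_lowrank_gp_basis(cbind(runif(n), runif(n)), rank = 8,
                                range_h = 0.5)
  y <- rnorm(n)
  gammas <- c(1e4, 10, 0.1, 1e-4)
  edofs <- vapply(gammas, function(g) {
    fit_gaussian_mem_reml(y, rep(1, n), X, blk, fixed_gamma = g)$edof
  }, 1)
  expect_true(all(diff(edofs) < 1e-8)) # non-increasing as penalty grows
  expect_true(all(edofs <= ncol(X) + ncol(blk$Z) + 1e-8))
  expect_true(all(edofs >= ncol(X) - 1e-8))
})

test_that("penalized-WLS coefficients match the normal-equations oracle", {
  set.seed(14)
  for (s in 1:10) {
    n <- 25
    X <- cbind(1, rnorm(n))
    blk <- build_lowrank_gp_basis(cbind(runif(n), runif(n)), rank = 5,
                                  range_h = 0.6)
    w <- runif(n, 0.5, 3)
    y <- rnorm(n)
    g <- runif(1, 0.05, 5)
    fit <- fit_gaussian_mem_reml(y, w, X, blk, fixed_gamma = g)
    Xt <- cbind(X, blk$Z)
    pen <- c(0, 0, rep(1 / g, ncol(blk$Z)))
    expect_equal(unname(fit$beta), oracle_penalized_wls(Xt, w, y, pen),
                 tolerance = 1e-10)
  }
})

test_that("mixed two-step fit degenerates exactly to the fixed-effects fit", {
  d <- make_random_dataset(n = 50, beta = c(0.5, 1), seed = 31, sigma2 = 2)
  mm <- fit_mem_proposed(d, redesign = NULL)
  ff <- fit_proposed(d)
  expect_equal(unname(mm$beta), unname(ff$beta), tolerance = 1e-12)
  expect_equal(mm$sigma2, ff$sigma2, tolerance = 1e-12)
  expect_equal(unname(mm$cov_beta), unname(ff$cov_beta), tolerance = 1e-12)
  expect_equal(mm$edof, ncol(d$X), tolerance = 1e-10)
})

test_that("penalized estimators reduce to the unpenalized forms at zero penalty", {
  # Evaluating the mixed-model normal equations with a zero penalty must
  # reproduce the fixed-effects closed forms at the same fitted means
  d <- make_random_dataset(n = 60, beta = c(0.8, 0.6), seed = 32, sigma2 = 2)
  ff <- fit_proposed(d)
  lam <- ff$lambda_plus
  wresp <- log(lam / d$z) + (d$y - lam) / lam
  A <- t(d$X * lam) %*% d$X
  beta0 <- unname(drop(solve(A, t(d$X * lam) %*% wresp)))
  expect_equal(unname(ff$beta), beta0, tolerance = 1e-10)
  L <- sum(diag(solve(A) %*% A))
  expect_equal(L, ncol(d$X), tolerance = 1e-12)
})

test_that("taylor mixed fit with no random blocks equals the comparator fit", {
  d <- make_random_dataset(n = 40, beta = c(0.5, 0.7), seed = 33)
  mm <- fit_mem_comparator(d, NULL, method = "taylor")
  ff <- fit_comparator(d, "taylor")
  expect_equal(unname(mm$beta), unname(ff$beta), tolerance = 1e-10)
  expect_equal(mm$sigma2, ff$sigma2, tolerance = 1e-10)
})

test_that("poisson mixed fit matches the fixed MLE when shrinkage is negligible", {
  set.seed(34)
  n <- 150
  X <- cbind(1, rnorm(n))
  lambda <- exp(drop(X %*% c(3, 0.5))) # large counts, no random signal
  y <- rpois(n, lambda)
  d <- count_dataset(y, X = X,
                     groups = list(g = factor(rep(1:5, length.out = n))))
  blk <- build_group_design(d$groups$g)
  mm <- fit_mem_comparator(d, blk, method = "poisson")
  ml <- fit_irls_poisson(d)
  expect_equal(unname(mm$beta[2]), unname(ml$beta[2]), tolerance = 0.05)
  expect_identical(mm$sigma2, 1)
})

test_that("odpoisson mixed dispersion lands in the sampling band", {
  set.seed(35)
  sig <- replicate(10, {
    cfg <- scenario_config(n = 200, beta0 = 1, sigma2 = 1,
                           groups = list(n_groups = 8, effect_sd = 0.5),
                           seed = sample.int(1e6, 1), n_iter = 1)
    sim <- gen_scenario_dataset(cfg, 1)
    blk <- build_group_design(sim$data$groups$group)
    fit_mem_comparator(sim$data, blk, method = "odpoisson")$sigma2
  })
  expect_gt(mean(sig), 0.7)
  expect_lt(mean(sig), 1.4)
})

test_that("proposed mixed fit recovers a spatial field about as well as PQL", {
  cfg <- scenario_config(n = 150, beta0 = 0, sigma2 = 5,
                         spatial = list(rank = 30), seed = 36, n_iter = 1)
  sim <- gen_scenario_dataset(cfg, 1)
  blk <- build_lowrank_gp_basis(sim$data$coords, rank = 30)
  fp <- fit_mem_proposed(sim$data, blk)
  fo <- fit_mem_comparator(sim$data, blk, method = "odpoisson")
  r_p <- sqrt(mean((fp$random_effects[[1]] - sim$truth$s)^2))
  r_o <- sqrt(mean((fo$random_effects[[1]] - sim$truth$s)^2))
  expect_lt(r_p, 1.3 * r_o)
  expect_true(all(fp$tau2 >= 0))
  expect_gte(fp$edof, 3)
})
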