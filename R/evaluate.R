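# Monte Carlo experiment runner and the evaluation metrics: RMSE, mean
# bias, standard-error calibration ratio, and spatial-effect RMSE.

#' RMSE and mean bias of a set of estimates
#'
#' `bias = mean(est - truth)`; `rmse = sqrt(mean((est - truth)^2))`, both
#' averaged over the estimates supplied (i.e. over Monte Carlo iterations).
#'
#' @param estimates Numeric vector of per-iteration estimates.
#' @param truth True parameter value.
#' @return A list with `rmse` and `bias`.
#' @export
#' @examples
#' rmse_bias(c(1, 3), 2) # rmse 1, bias 0
rmse_bias <- function(estimates, truth) {
  if (length(estimates) < 1L) stop("need at least one estimate", call. = FALSE)
  d <- estimates - truth
  list(rmse = sqrt(mean(d^2)), bias = mean(d))
}

#' Standard-error calibration ratio
#'
#' The mean estimated standard error divided by the empirical standard
#' deviation of the estimates across iterations. Values near 1 indicate the
#' model-based SEs correctly measure the sampling variability; below 1,
#' underestimation.
#'
#' @param ses Per-iteration estimated standard errors.
#' @param estimates Per-iteration point estimates.
#' @return A single ratio.
#' @export
se_ratio <- function(ses, estimates) {
  if (length(estimates) < 2L) stop("need at least two iterations", call. = FALSE)
  emp_sd <- stats::sd(estimates)
  if (emp_sd == 0) stop("empirical SD of estimates is zero: ratio undefined",
                        call. = FALSE)
  mean(ses) / emp_sd
}

fit_one_method <- function(data, method, redesign_builder, model) {
  if (model == "fixed") {
    fit_count_glm(data, method = method)
  } else {
    redesign <- redesign_builder(data)
    if (method == "proposed") {
      fit_mem_proposed(data, redesign)
    } else {
      fit_mem_comparator(data, redesign, method = method)
    }
  }
}

#' Run a Monte Carlo estimator comparison
#'
#' For each replication of a scenario, generates a dataset, fits each
#' requested estimator, and records coefficient estimates, standard errors,
#' and convergence. Individual fit failures (divergence, non-convergence)
#' are caught and counted — never aborting the experiment — and excluded
#' from the summary statistics, with the excluded fraction reported as
#' `divergence_rate`. With `model = "spatial"` (or `"grouped"`) a low-rank
#' GP (or group-intercept) random effect is added to every mixed fit, and
#' the per-iteration RMSE of the recovered effect against the simulated
#' truth is averaged into the summary.
#'
#' @param config A [scenario_config()].
#' @param methods Estimator names; see [fit_count_glm()] for the fixed case
#'   (`"poisson"`, `"odpoisson"`, `"negbin"`, `"loglinear"`, `"taylor"`,
#'   `"proposed"`) and [fit_mem_comparator()] for the mixed case
#'   (`"poisson"`, `"odpoisson"`, `"taylor"`, `"proposed"`).
#' @param model `"fixed"`, `"spatial"`, or `"grouped"`.
#' @return An `experiment_result`: list with `per_iteration` (data frame of
#'   iteration, method, parameter, estimate, se, converged), `summary`
#'   (method, parameter, rmse, bias, mean_se, se_ratio, divergence_rate,
#'   and `effect_rmse` for mixed models), and `config`.
#' @export
run_experiment <- function(config, methods = c("poisson", "proposed"),
                           model = c("fixed", "spatial", "grouped")) {
  model <- match.arg(model)
  stopifnot(inherits(config, "scenario_config"))
  if (model == "spatial" && is.null(config$spatial)) {
    stop("model = 'spatial' requires a spatial component in the config",
         call. = FALSE)
  }
  if (model == "grouped" && is.null(config$groups)) {
    stop("model = 'grouped' requires a group component in the config",
         call. = FALSE)
  }
  redesign_builder <- switch(model,
    fixed = NULL,
    spatial = function(d) build_lowrank_gp_basis(
      d$coords, rank = config$spatial$rank, range_h = config$spatial$range_h),
    grouped = function(d) build_group_design(d$groups[[1L]]))

  rows <- vector("list", config$n_iter * length(methods))
  effect_rmse <- stats::setNames(
    lapply(methods, function(m) numeric(0)), methods)
  ri <- 0L
  for (j in seq_len(config$n_iter)) {
    sim <- gen_scenario_dataset(config, j)
    truth_beta <- sim$truth$beta
    for (m in methods) {
      ri <- ri + 1L
      fit <- tryCatch(fit_one_method(sim$data, m, redesign_builder, model),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[ri]] <- data.frame(iteration = j, method = m,
                                 parameter = names(truth_beta),
                                 estimate = NA_real_, se = NA_real_,
                                 sigma2 = NA_real_, converged = FALSE)
        next
      }
      ixf <- seq_along(truth_beta)
      se <- sqrt(pmax(diag(fit$cov_beta)[ixf], 0))
      rows[[ri]] <- data.frame(iteration = j, method = m,
                               parameter = names(truth_beta),
                               estimate = unname(fit$beta[ixf]),
                               se = unname(se), sigma2 = fit$sigma2,
                               converged = isTRUE(fit$converged))
      if (model != "fixed") {
        truth_eff <- if (model == "spatial") sim$truth$s else sim$truth$g
        est_eff <- fit$random_effects[[1L]]
        effect_rmse[[m]] <- c(effect_rmse[[m]],
                              sqrt(mean((est_eff - truth_eff)^2)))
      }
    }
  }
  per_iter <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(methods, function(m) {
    sub <- per_iter[per_iter$method == m, , drop = FALSE]
    n_it <- length(unique(sub$iteration))
    ok <- sub[sub$converged, , drop = FALSE]
    div_rate <- 1 - length(unique(ok$iteration)) / n_it
    pars <- unique(sub$parameter)
    out <- lapply(pars, function(p) {
      e <- ok[ok$parameter == p, , drop = FALSE]
      truth <- config_truth(config)[p]
      if (nrow(e) == 0) {
        return(data.frame(method = m, parameter = p, rmse = NA_real_,
                          bias = NA_real_, mean_se = NA_real_,
                          se_ratio = NA_real_, mean_sigma2 = NA_real_,
                          divergence_rate = div_rate,
                          effect_rmse = NA_real_))
      }
      rb <- rmse_bias(e$estimate, truth)
      sr <- if (nrow(e) >= 2 && stats::sd(e$estimate) > 0) {
        se_ratio(e$se, e$estimate)
      } else NA_real_
      data.frame(method = m, parameter = p, rmse = rb$rmse, bias = rb$bias,
                 mean_se = mean(e$se), se_ratio = sr,
                 mean_sigma2 = mean(e$sigma2),
                 divergence_rate = div_rate,
                 effect_rmse = if (length(effect_rmse[[m]])) {
                   mean(effect_rmse[[m]])
                 } else NA_real_)
    })
    do.call(rbind, out)
  }))
  rownames(summ) <- NULL

  structure(list(per_iteration = per_iter, summary = summ, config = config),
            class = "experiment_result")
}

# True coefficient vector (named) implied by a scenario config.
config_truth <- function(config) {
  setNames(c(config$beta0, config$beta),
           c("(Intercept)", paste0("x", seq_along(config$beta))))
}

#' @export
print.experiment_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Monte Carlo experiment: N = %d, beta0 = %g, sigma^2 = %g, %d replications\n",
    cfg$n, cfg$beta0, cfg$sigma2, cfg$n_iter))
  print(x$summary, digits = 4)
  invisible(x)
}
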