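# Dataset readers/writers, model-specification parsing, and report
# serialisation backing the command-line interface.

#' Model specification for CSV-backed fits
#'
#' Names the columns of a CSV file that play each role in the model, plus
#' the estimator and its options. Group terms each contribute a random
#' intercept; a spatial term adds a low-rank GP on the named coordinate
#' columns.
#'
#' @param response Response column name (required).
#' @param fixed_terms Covariate column names (may be empty: intercept-only).
#' @param offset Optional offset column name.
#' @param group_terms Character vector of categorical columns.
#' @param spatial_term Optional list with `coords` (two column names) and
#'   optional `rank`, `range_h`.
#' @param method Estimator name.
#' @param method_options List of estimator options (`c`, `max_iter`, `tol`,
#'   `reml`).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, fixed_terms = character(), offset = NULL,
                       group_terms = character(), spatial_term = NULL,
                       method = "proposed", method_options = list()) {
  if (missing(response) || !nzchar(response)) {
    stop("'response' column is required", call. = FALSE)
  }
  methods <- c("poisson", "odpoisson", "negbin", "loglinear", "taylor",
               "proposed")
  if (!method %in% methods) {
    stop(sprintf("unknown method '%s'; must be one of %s", method,
                 paste(methods, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(spatial_term)) {
    if (is.character(spatial_term)) spatial_term <- list(coords = spatial_term)
    if (length(spatial_term$coords) != 2L) {
      stop("'spatial_term$coords' must name two coordinate columns",
           call. = FALSE)
    }
  }
  opts <- utils::modifyList(
    list(c = 0.5, max_iter = 100L, tol = 1e-8, reml = "REML"),
    method_options)
  structure(list(response = response, offset = offset,
                 fixed_terms = as.character(fixed_terms),
                 group_terms = as.character(group_terms),
                 spatial_term = spatial_term, method = method,
                 method_options = opts),
            class = "model_spec")
}

#' Read a model specification from YAML
#'
#' @param path YAML file with keys matching the [model_spec()] arguments.
#' @return A `model_spec`.
#' @export
read_model_spec <- function(path) {
  # keep bare y/n column names as strings (YAML 1.1 would read them as booleans)
  handlers <- list(
    "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
    "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x)
  raw <- yaml::read_yaml(path, handlers = handlers)
  do.call(model_spec, raw[intersect(names(raw), names(formals(model_spec)))])
}

#' Read a count dataset from CSV according to a model specification
#'
#' Validates every used column: the response must be non-negative integer,
#' offsets positive, covariates and coordinates numeric and finite. Rows
#' with missing values in any used column are dropped with a message
#' reporting the count. Errors name the offending column and the first
#' offending row.
#'
#' @param path CSV file with a header row.
#' @param spec A [model_spec()].
#' @return A [count_dataset()].
#' @export
read_count_dataset <- function(path, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  used <- c(spec$response, spec$offset, spec$fixed_terms, spec$group_terms,
            spec$spatial_term$coords)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols)) {
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cc <- stats::complete.cases(df[, used, drop = FALSE])
  if (!all(cc)) {
    message(sprintf("dropping %d row(s) with missing values in used columns",
                    sum(!cc)))
    df <- df[cc, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no complete rows in input", call. = FALSE)

  y <- df[[spec$response]]
  if (!is.numeric(y) || any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    bad <- which(!is.finite(y) | y < 0 | abs(y - round(y)) > 1e-8)[1L]
    stop(sprintf("column '%s' must hold non-negative integer counts (row %d)",
                 spec$response, bad), call. = FALSE)
  }
  z <- if (is.null(spec$offset)) 1 else df[[spec$offset]]
  if (!is.null(spec$offset) && (!is.numeric(z) || any(!is.finite(z)) ||
                                any(z <= 0))) {
    stop(sprintf("offsets must be positive (column '%s')", spec$offset),
         call. = FALSE)
  }
  X <- if (length(spec$fixed_terms)) {
    as.matrix(cbind(`(Intercept)` = 1, df[, spec$fixed_terms, drop = FALSE]))
  } else {
    matrix(1, nrow(df), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  groups <- if (length(spec$group_terms)) {
    stats::setNames(lapply(spec$group_terms, function(g) factor(df[[g]])),
                    spec$group_terms)
  } else NULL
  coords <- if (!is.null(spec$spatial_term)) {
    as.matrix(df[, spec$spatial_term$coords, drop = FALSE])
  } else NULL
  count_dataset(y = y, X = X, z = z, groups = groups, coords = coords)
}

#' Write a generated dataset to CSV (plus a JSON truth sidecar)
#'
#' Columns: `y`, `z`, covariates `x1..xK` (intercept column omitted), any
#' group labels, and `coord_x`/`coord_y` when coordinates are present.
#'
#' @param sim Output of [gen_scenario_dataset()] (or a bare
#'   [count_dataset()]).
#' @param path Output CSV path.
#' @param truth_path Optional JSON path for the truth record.
#' @return `path`, invisibly.
#' @export
write_count_dataset <- function(sim, path, truth_path = NULL) {
  data <- if (inherits(sim, "count_dataset")) sim else sim$data
  Xc <- data$X[, colnames(data$X) != "(Intercept)", drop = FALSE]
  df <- data.frame(y = data$y, z = data$z)
  if (ncol(Xc)) df <- cbind(df, as.data.frame(Xc))
  if (!is.null(data$groups)) {
    for (g in names(data$groups)) df[[g]] <- as.character(data$groups[[g]])
  }
  if (!is.null(data$coords)) {
    df$coord_x <- data$coords[, 1L]
    df$coord_y <- data$coords[, 2L]
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path) && !inherits(sim, "count_dataset")) {
    jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Fit a model described by a specification to a dataset
#'
#' The single entry point behind the CLI `fit` subcommand: builds any
#' random-effect design named by the spec and dispatches to the matching
#' estimator.
#'
#' @param data A [count_dataset()].
#' @param spec A [model_spec()].
#' @return A `fixed_fit` or `mixed_fit`.
#' @export
fit_model_spec <- function(data, spec) {
  stopifnot(inherits(data, "count_dataset"), inherits(spec, "model_spec"))
  blocks <- list()
  for (g in spec$group_terms) {
    blocks[[length(blocks) + 1L]] <- build_group_design(data$groups[[g]], name = g)
  }
  if (!is.null(spec$spatial_term)) {
    blocks[[length(blocks) + 1L]] <- build_lowrank_gp_basis(
      data$coords, rank = spec$spatial_term$rank,
      range_h = spec$spatial_term$range_h, name = "spatial")
  }
  opts <- spec$method_options
  if (length(blocks) == 0L) {
    fit_count_glm(data, method = spec$method, c = opts$c)
  } else if (spec$method == "proposed") {
    fit_mem_proposed(data, blocks, method = opts$reml)
  } else if (spec$method %in% c("poisson", "odpoisson", "taylor")) {
    fit_mem_comparator(data, blocks, method = spec$method, c = opts$c,
                       reml = opts$reml)
  } else {
    stop(sprintf("method '%s' does not support random effects", spec$method),
         call. = FALSE)
  }
}

#' Serialise a fit to a machine-readable report
#'
#' @param fit A `fixed_fit` or `mixed_fit`.
#' @param spec The [model_spec()] used (echoed into the report).
#' @param path Optional JSON output path.
#' @param r Zero ratio of the fitted response, echoed for the log.
#' @return The report list, invisibly if written.
#' @export
fit_report <- function(fit, spec = NULL, path = NULL, r = NULL) {
  ct <- coef_table(fit)
  if (inherits(fit, "mixed_fit")) ct <- ct[seq_len(fit$n_fixed), , drop = FALSE]
  rep <- list(
    method = fit$method,
    coefficients = ct,
    sigma2 = fit$sigma2,
    converged = isTRUE(fit$converged),
    n_iter = fit$n_iter,
    zero_ratio = r,
    edof = if (inherits(fit, "mixed_fit")) fit$edof else length(fit$beta),
    tau2 = if (inherits(fit, "mixed_fit")) as.list(fit$tau2) else NULL,
    spec = if (!is.null(spec)) unclass(spec) else NULL,
    fitted = unname(fit$lambda_hat))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
    return(invisible(rep))
  }
  rep
}
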