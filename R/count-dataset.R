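#' Construct a count dataset
#'
#' Bundles a count response with its offset, design matrix, and optional
#' grouping labels and planar coordinates, validating the invariants every
#' estimator in the package relies on.
#'
#' @param y Non-negative integer counts (length N).
#' @param X Numeric design matrix (N x K) of covariates. A leading column of
#'   ones is the usual way to include an intercept. A vector is treated as a
#'   single column. If `NULL`, an intercept-only design is used.
#' @param z Positive offsets (length N or scalar); defaults to 1. The offset
#'   multiplies the mean, i.e. `lambda_i = z_i * exp(x_i' beta)`.
#' @param groups Optional named list of factors/character vectors (length N
#'   each), one random intercept per element.
#' @param coords Optional N x 2 matrix of planar coordinates for spatial
#'   random effects.
#'
#' @return An object of class `count_dataset`: a list with elements `y`, `z`,
#'   `X`, `groups`, `coords`, and `n`.
#' @export
#' @examples
#' d <- count_dataset(y = c(0, 2, 5), X = cbind(1, c(-1, 0, 1)))
#' d$n
count_dataset <- function(y, X = NULL, z = 1, groups = NULL, coords = NULL) {
  if (length(y) < 1L) stop("'y' must have length >= 1", call. = FALSE)
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("'y' contains missing or non-finite values", call. = FALSE)
  }
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    bad <- which(y < 0 | abs(y - round(y)) > 1e-8)[1L]
    stop(sprintf("counts must be non-negative integers (row %d: %g)", bad, y[bad]),
         call. = FALSE)
  }
  y <- round(y)
  n <- length(y)

  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("'X' must have one row per count", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("'X' contains missing or non-finite values", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("'X' is rank-deficient: columns are linearly dependent", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  if (length(z) == 1L) z <- rep(as.numeric(z), n)
  z <- as.numeric(z)
  if (length(z) != n) stop("'z' must be scalar or length N", call. = FALSE)
  if (anyNA(z) || any(!is.finite(z)) || any(z <= 0)) {
    stop("offsets must be positive and finite", call. = FALSE)
  }

  if (!is.null(groups)) {
    if (!is.list(groups)) groups <- list(group = groups)
    if (is.null(names(groups)) || any(names(groups) == "")) {
      names(groups) <- paste0("group", seq_along(groups))
    }
    groups <- lapply(groups, function(g) {
      g <- as.factor(g)
      if (length(g) != n) stop("each group vector must have length N", call. = FALSE)
      g
    })
  }

  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != n || ncol(coords) != 2L) {
      stop("'coords' must be an N x 2 matrix", call. = FALSE)
    }
    if (anyNA(coords) || any(!is.finite(coords))) {
      stop("'coords' contains missing or non-finite values", call. = FALSE)
    }
  }

  structure(
    list(y = y, z = z, X = X, groups = groups, coords = coords, n = n),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("Count dataset: N = %d, K = %d covariate column(s)\n",
              x$n, ncol(x$X)))
  cat(sprintf("  zero ratio r = %.3f; offsets %s\n", zero_ratio(x$y),
              if (all(x$z == 1)) "all 1" else "supplied"))
  if (!is.null(x$groups)) {
    cat("  groups:", paste(sprintf("%s (%d levels)", names(x$groups),
                                   vapply(x$groups, nlevels, 1L)),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$coords)) cat("  planar coordinates present\n")
  invisible(x)
}
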