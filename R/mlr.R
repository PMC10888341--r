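# Multiple linear regression by ordinary least squares (SVD-based
# minimum-norm solution, the numerical-least-squares standard).

#' Fit a multiple linear regression
#'
#' Ordinary least squares of a real target on the feature columns plus an
#' intercept. The solution is computed from the singular value
#' decomposition of the design matrix: with a full-rank design this is the
#' unique OLS solution (identical to the normal equations); with exactly
#' collinear features — which arise for noiseless colour data, where all
#' three normalized channels are affine in the blend fraction — it is the
#' minimum-norm least-squares solution, which still reproduces the fitted
#' subspace exactly. A design whose feature block carries no information at
#' all (rank < 2 including the intercept) is an error.
#'
#' @param X Numeric matrix (n x d).
#' @param y Numeric targets of length n; requires `n > d + 1`.
#' @param tol Relative singular-value tolerance for rank truncation.
#' @return Object of class `mlr_model` with `coefficients` (length d),
#'   `intercept` and the effective `rank` of the design.
#' @export
fit_mlr <- function(X, y, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  if (length(y) != n) stop("X and y lengths differ", call. = FALSE)
  if (n <= d + 1L)
    stop("need n > d + 1 observations (n = ", n, ", d = ", d, ")",
         call. = FALSE)
  design <- cbind(`(Intercept)` = 1, X)
  sv <- svd(design)
  keep <- sv$d > tol * sv$d[1L]
  rank <- sum(keep)
  if (rank < 2L)
    stop("rank-deficient design: features carry no information",
         call. = FALSE)
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  structure(list(intercept = beta[1L], coefficients = beta[-1L],
                 rank = rank, d = d),
            class = "mlr_model")
}

#' Predict with a fitted MLR model
#'
#' @param model An `mlr_model`.
#' @param X Numeric matrix (m x d).
#' @return Numeric vector of predictions `X beta + intercept`.
#' @export
predict_mlr <- function(model, X) {
  stopifnot(inherits(model, "mlr_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("feature dimension mismatch", call. = FALSE)
  drop(X %*% model$coefficients) + model$intercept
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d features (rank %d), intercept %.4g\n",
              x$d, x$rank, x$intercept))
  invisible(x)
}
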