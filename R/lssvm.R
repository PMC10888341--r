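# Least-squares support vector machine with an RBF kernel.
#
# The LS-SVM replaces the SVM quadratic program with one linear system in the
# dual coefficients and the bias:
#
#   [ 0   1'            ] [ b     ]   [ 0 ]
#   [ 1   K + I/gamma   ] [ alpha ] = [ y ]
#
# where K is the kernel matrix on the calibration points, gamma the
# regularization constant, and f(x) = sum_i alpha_i k(x, x_i) + b.
# Classification uses targets y in {-1, +1} per one-vs-rest machine;
# because the system matrix does not depend on y, all one-vs-rest machines
# are obtained from a single multi-RHS solve.

#' Radial basis function kernel matrix
#'
#' `K[i, j] = exp(-||a_i - b_j||^2 / (2 * sigma2))`; symmetric with unit
#' diagonal when `A` and `B` coincide.
#'
#' @param A Numeric matrix (n x d).
#' @param B Numeric matrix (m x d); defaults to `A`.
#' @param sigma2 Positive squared bandwidth.
#' @return n x m kernel matrix.
#' @export
rbf_kernel <- function(A, B = A, sigma2) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("dimension mismatch", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("`sigma2` must be positive", call. = FALSE)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sigma2))
}

# Solve the LS-SVM dual system for one or more target columns Y (n x L).
# Returns list(bias = length-L vector, alpha = n x L matrix).
lssvm_solve <- function(K, Y, gamma) {
  n <- nrow(K)
  Y <- as.matrix(Y)
  M <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(n) / gamma))
  sol <- tryCatch(solve(M, rbind(0, Y)),
                  error = function(e)
                    stop("LS-SVM system numerically singular; consider a ",
                         "smaller gamma (larger 1/gamma jitter): ",
                         conditionMessage(e), call. = FALSE))
  list(bias = sol[1L, ], alpha = sol[-1L, , drop = FALSE])
}

#' Fit an LS-SVM model
#'
#' For regression, fits a single machine on the real targets. For
#' classification, fits one-vs-rest machines (target +1 for the class, -1
#' for the rest) for every label; with exactly two classes the two machines
#' are exact negations of each other, so the scheme reduces to the binary
#' machine.
#'
#' @param X Numeric calibration matrix (n x d).
#' @param y Real targets (regression) or class labels (classification).
#' @param gamma Positive regularization constant.
#' @param sigma2 Positive squared RBF bandwidth.
#' @param task `"regression"` or `"classification"`.
#' @return Object of class `lssvm_model` with the calibration points, dual
#'   coefficients (`alpha`, one column per machine), `bias`, hyperparameters
#'   and, for classification, the ordered `labels`.
#' @export
fit_lssvm <- function(X, y, gamma, sigma2,
                      task = c("regression", "classification")) {
  task <- match.arg(task)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 calibration samples", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be positive", call. = FALSE)
  K <- rbf_kernel(X, X, sigma2 = sigma2)
  if (task == "regression") {
    y <- as.numeric(y)
    if (length(y) != n) stop("X and y lengths differ", call. = FALSE)
    sol <- lssvm_solve(K, y, gamma)
    labels <- NULL
  } else {
    y <- as.character(y)
    if (length(y) != n) stop("X and y lengths differ", call. = FALSE)
    labels <- sort(unique(y))
    if (length(labels) < 2L) stop("need >= 2 classes", call. = FALSE)
    Y <- vapply(labels, function(l) ifelse(y == l, 1, -1), numeric(n))
    sol <- lssvm_solve(K, Y, gamma)
  }
  structure(list(X = X, alpha = sol$alpha, bias = sol$bias,
                 gamma = gamma, sigma2 = sigma2, task = task,
                 labels = labels, d = ncol(X)),
            class = "lssvm_model")
}

#' Predict with a fitted LS-SVM model
#'
#' Decision values are `f(x) = sum_i alpha_i k(x, x_i) + bias`, one column
#' per one-vs-rest machine. For classification, `type = "response"` returns
#' the label of the machine with the largest decision value (argmax; for two
#' classes this is the sign rule), ties going to the first label in class
#' order. For regression both types return the real prediction.
#'
#' @param model An `lssvm_model`.
#' @param X Numeric matrix (m x d).
#' @param type `"response"` (labels / real predictions) or `"decision"`
#'   (raw decision-value matrix).
#' @return See `type`.
#' @export
predict_lssvm <- function(model, X, type = c("response", "decision")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "lssvm_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("feature dimension mismatch", call. = FALSE)
  Kx <- rbf_kernel(X, model$X, sigma2 = model$sigma2)
  dec <- sweep(Kx %*% model$alpha, 2L, model$bias, `+`)
  if (model$task == "regression") return(drop(dec))
  if (type == "decision") {
    colnames(dec) <- model$labels
    return(dec)
  }
  model$labels[max.col(dec, ties.method = "first")]
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("<lssvm_model %s> n=%d gamma=%.4g sigma2=%.4g%s\n",
              x$task, nrow(x$X), x$gamma, x$sigma2,
              if (is.null(x$labels)) ""
              else paste0(" classes=", paste(x$labels, collapse = ","))))
  invisible(x)
}

#' Hyperparameter grid for LS-SVM tuning
#'
#' @param gamma_values Positive regularization candidates; default
#'   `10^(-1:4)`.
#' @param sigma2_values Positive squared-bandwidth candidates; default
#'   `10^(-3:2)`.
#' @param cv_folds Number of cross-validation folds, >= 2 (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @return Object of class `hyper_grid`.
#' @export
hyperparameter_grid <- function(gamma_values = 10^(-1:4),
                                sigma2_values = 10^(-3:2),
                                cv_folds = 10L, seed = 1L) {
  if (length(gamma_values) == 0L || any(gamma_values <= 0))
    stop("`gamma_values` must be a nonempty positive vector", call. = FALSE)
  if (length(sigma2_values) == 0L || any(sigma2_values <= 0))
    stop("`sigma2_values` must be a nonempty positive vector", call. = FALSE)
  cv_folds <- as.integer(cv_folds)
  if (is.na(cv_folds) || cv_folds < 2L)
    stop("`cv_folds` must be >= 2", call. = FALSE)
  structure(list(gamma_values = sort(gamma_values),
                 sigma2_values = sort(sigma2_values),
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "hyper_grid")
}

#' @rdname hyperparameter_grid
#' @export
default_grid <- function(seed = 1L) hyperparameter_grid(seed = seed)

# Deterministic fold assignment; stratified by class when y is given, so no
# training fold can lose a class entirely (each class is dealt across folds).
make_folds <- function(n, k, y = NULL, seed = 1L) {
  k <- min(k, n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  folds <- integer(n)
  if (is.null(y)) {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    offset <- 0L
    for (l in sort(unique(as.character(y)))) {
      idx <- which(y == l)
      # rotate fold labels between classes so small classes spread evenly
      lab <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      folds[idx[sample.int(length(idx))]] <- lab
      offset <- offset + length(idx)
    }
  }
  folds
}

#' Tune LS-SVM hyperparameters by grid search
#'
#' Exhaustive search over the grid, scored by k-fold cross-validation on the
#' calibration data only: misclassification rate for classification
#' (stratified folds), RMSE for regression. Ties are broken toward the
#' smallest gamma, then the smallest sigma2. Deterministic given the grid
#' seed.
#'
#' @param X Numeric calibration matrix.
#' @param y Targets or labels.
#' @param grid A [hyperparameter_grid()].
#' @param task `"regression"` or `"classification"`.
#' @return List with `gamma`, `sigma2`, `cv_score` (the best CV loss) and
#'   `scores` (full loss matrix, gamma x sigma2).
#' @export
tune_lssvm <- function(X, y, grid = default_grid(),
                       task = c("regression", "classification")) {
  task <- match.arg(task)
  stopifnot(inherits(grid, "hyper_grid"))
  X <- as.matrix(X)
  n <- nrow(X)
  strat <- if (task == "classification") as.character(y) else NULL
  folds <- make_folds(n, grid$cv_folds, y = strat, seed = grid$seed)
  n_fold <- max(folds)
  scores <- matrix(NA_real_,
                   nrow = length(grid$gamma_values),
                   ncol = length(grid$sigma2_values),
                   dimnames = list(gamma = grid$gamma_values,
                                   sigma2 = grid$sigma2_values))
  for (si in seq_along(grid$sigma2_values)) {
    s2 <- grid$sigma2_values[si]
    for (gi in seq_along(grid$gamma_values)) {
      g <- grid$gamma_values[gi]
      loss <- 0
      for (fd in seq_len(n_fold)) {
        hold <- folds == fd
        m <- fit_lssvm(X[!hold, , drop = FALSE],
                       if (task == "regression") y[!hold]
                       else strat[!hold],
                       gamma = g, sigma2 = s2, task = task)
        pred <- predict_lssvm(m, X[hold, , drop = FALSE])
        loss <- loss + if (task == "regression")
          sum((y[hold] - pred)^2) else sum(pred != strat[hold])
      }
      scores[gi, si] <- if (task == "regression") sqrt(loss / n) else loss / n
    }
  }
  # first minimum scanning gamma ascending within sigma2 ascending would
  # break ties on sigma2 first; tie order is smallest gamma, then sigma2
  best <- which(scores == min(scores), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  list(gamma = grid$gamma_values[best[1L]],
       sigma2 = grid$sigma2_values[best[2L]],
       cv_score = min(scores), scores = scores)
}
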