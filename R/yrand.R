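# y-randomization (response permutation) robustness test: the features are
# held fixed, the targets are shuffled, the model is refit with the same
# protocol and scored on the calibration samples. Genuine structure
# collapses the permuted scores toward chance.

#' y-randomization permutation test
#'
#' @param fit_fn Model-fitting contract: `function(X, y_perm)` that refits
#'   the model on the permuted targets with the same protocol (including any
#'   hyperparameter tuning), scores it on the calibration samples, and
#'   returns a named numeric vector of scores.
#' @param X Calibration feature matrix (held fixed).
#' @param y Original targets; every permutation preserves their multiset.
#' @param n_permutations Number of random permutations (>= 1); default 100.
#' @param seed Integer seed making the permutation stream reproducible.
#' @param permutations Optional list of explicit index vectors overriding the
#'   random permutations (test hook; e.g. the identity permutation).
#' @return Object of class `yrand_result`: `scores` (one row per successful
#'   permutation), `mean_scores`, `n_permutations`, `n_failed`, `seed`.
#' @export
y_randomization <- function(fit_fn, X, y, n_permutations = 100L, seed = 1L,
                            permutations = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("X and y lengths differ", call. = FALSE)
  if (is.null(permutations)) {
    n_permutations <- as.integer(n_permutations)
    if (is.na(n_permutations) || n_permutations < 1L)
      stop("`n_permutations` must be >= 1", call. = FALSE)
    set.seed(seed)
    permutations <- replicate(n_permutations, sample.int(n),
                              simplify = FALSE)
  } else {
    n_permutations <- length(permutations)
  }
  rows <- list()
  n_failed <- 0L
  for (p in permutations) {
    stopifnot(length(p) == n)
    res <- tryCatch(fit_fn(X, y[p]), error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L
    else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L)
    stop("every y-randomization refit failed", call. = FALSE)
  scores <- do.call(rbind, rows)
  structure(list(scores = scores, mean_scores = colMeans(scores),
                 n_permutations = n_permutations, n_failed = n_failed,
                 seed = as.integer(seed)),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("<yrand_result> %d permutations (%d failed)\n",
              x$n_permutations, x$n_failed))
  print(round(x$mean_scores, 4))
  invisible(x)
}
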