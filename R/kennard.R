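# Kennard-Stone sample-set partitioning: deterministic greedy selection of a
# calibration subset that spans the feature space uniformly.

#' Kennard-Stone selection
#'
#' Selects `k` of `n` points: the first two are a pair at maximum Euclidean
#' distance; every further point maximizes its minimum distance to the points
#' already selected. Ties are broken toward the lowest row index, making the
#' selection fully deterministic.
#'
#' @param points Numeric matrix (n x d) of feature vectors.
#' @param k Number of points to select, `2 <= k <= n`.
#' @return Integer vector of length `k`, row indices in selection order.
#' @export
kennard_stone <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is.numeric(k) || length(k) != 1L || k != round(k))
    stop("`k` must be a single integer", call. = FALSE)
  k <- as.integer(k)
  if (k < 2L || k > n)
    stop("`k` must satisfy 2 <= k <= n (n = ", n, ")", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  # Max-distance pair; on ties, the first pair of the upper triangle in
  # column-major order (deterministic).
  d_upper <- d
  d_upper[lower.tri(d_upper, diag = TRUE)] <- -Inf
  start <- arrayInd(which.max(d_upper), dim(d))
  selected <- c(start[1L], start[2L])
  min_dist <- pmin(d[, selected[1L]], d[, selected[2L]])
  min_dist[selected] <- -Inf
  while (length(selected) < k) {
    nxt <- which.max(min_dist)  # ties -> lowest index
    selected <- c(selected, nxt)
    min_dist <- pmin(min_dist, d[, nxt])
    min_dist[nxt] <- -Inf
  }
  unname(as.integer(selected))
}

# round(fraction * n) with ties away from zero (base round() is banker's).
round_half_up <- function(x) floor(x + 0.5)

#' Kennard-Stone calibration/test split of a dataset
#'
#' Runs [kennard_stone()] on the pooled, unscaled (r, g, b) feature matrix
#' and assigns the selected rows to the calibration set, the remainder to the
#' test set. The calibration size is `round(fraction * n)` (ties away from
#' zero) unless overridden by an explicit count.
#'
#' @param ds An [oil_dataset()].
#' @param fraction Calibration share in (0, 1); default 0.7.
#' @param calibration_size Optional explicit calibration count overriding
#'   `fraction`.
#' @return Object of class `split_result` with fields `calibration` (row
#'   indices in selection order), `calibration_sorted`, `test` (sorted),
#'   `fraction`.
#' @export
split_dataset <- function(ds, fraction = 0.7, calibration_size = NULL) {
  stopifnot(inherits(ds, "oil_dataset"))
  n <- nrow(ds)
  if (is.null(calibration_size)) {
    if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
      stop("`fraction` must lie in (0, 1)", call. = FALSE)
    k <- round_half_up(fraction * n)
  } else {
    k <- as.integer(calibration_size)
    if (is.na(k) || k > n)
      stop("`calibration_size` must be an integer <= n = ", n, call. = FALSE)
  }
  if (k < 2L)
    stop("calibration size must be >= 2 (got ", k, ")", call. = FALSE)
  sel <- kennard_stone(features_matrix(ds), k)
  structure(
    list(calibration = sel,
         calibration_sorted = sort(sel),
         test = sort(setdiff(seq_len(n), sel)),
         fraction = fraction, n = n),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> n=%d calibration=%d test=%d\n",
              x$n, length(x$calibration), length(x$test)))
  invisible(x)
}

#' Write a split assignment as CSV
#'
#' Two columns: `sample_id` and `set` (`cal` or `test`), one row per sample
#' in dataset order.
#'
#' @param split A [split_dataset()] result.
#' @param ds The dataset the split refers to.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, ds, path) {
  stopifnot(inherits(split, "split_result"), inherits(ds, "oil_dataset"))
  set <- rep("test", nrow(ds))
  set[split$calibration] <- "cal"
  write.csv(data.frame(sample_id = ds$sample_id, set = set),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
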