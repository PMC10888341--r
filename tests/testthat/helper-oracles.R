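# Independent reference implementations used as oracles. These deliberately
# recompute everything from scratch (no shared code with the package paths
# they check).

# Exhaustive greedy Kennard-Stone: recomputes every candidate's minimum
# distance to the selected set at every step.
ks_oracle <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  edist <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  best <- c(NA, NA); best_d <- -Inf
  for (j in 2:n) for (i in 1:(j - 1)) {
    dij <- edist(i, j)
    if (dij > best_d) { best_d <- dij; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    mind <- vapply(cand, function(c)
      min(vapply(sel, function(s) edist(c, s), numeric(1))), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

# Kernel ridge closed form for the LS-SVM predictions: bias from the
# equality constraint, alpha from (K + I/gamma)^-1 (y - b).
kernel_ridge_oracle <- function(X, y, Xnew, gamma, sigma2) {
  sqd <- function(A, B)
    outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  K <- exp(-pmax(sqd(X, X), 0) / (2 * sigma2))
  A <- K + diag(nrow(X)) / gamma
  b <- sum(solve(A, y)) / sum(solve(A, rep(1, nrow(X))))
  alpha <- solve(A, y - b)
  drop(exp(-pmax(sqd(Xnew, X), 0) / (2 * sigma2)) %*% alpha) + b
}

# Metrics recomputed from realized label vectors, by direct counting.
metrics_from_vectors_oracle <- function(tp, tn, fp, fn) {
  y_true <- c(rep("pos", tp), rep("neg", tn), rep("neg", fp), rep("pos", fn))
  y_pred <- c(rep("pos", tp), rep("neg", tn), rep("pos", fp), rep("neg", fn))
  n <- length(y_true)
  TP <- sum(y_true == "pos" & y_pred == "pos")
  TN <- sum(y_true == "neg" & y_pred == "neg")
  FP <- sum(y_true == "neg" & y_pred == "pos")
  FN <- sum(y_true == "pos" & y_pred == "neg")
  pre <- if (TP + FP == 0) 0 else 100 * TP / (TP + FP)
  rec <- if (TP + FN == 0) 0 else 100 * TP / (TP + FN)
  acu <- 100 * (TP + TN) / n
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  m1 <- TP + FP; m2 <- TP + FN; m3 <- TN + FP; m4 <- TN + FN
  mcc <- if (m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0) 0 else
    (TP * TN - FP * FN) / sqrt(as.numeric(m1) * m2 * m3 * m4)
  c(PRE = pre, REC = rec, ACU = acu, ERR = 100 - acu, F1S = f1, MCC = mcc)
}

# Two well-separated 2-D Gaussian clusters for classifier sanity checks.
make_two_clusters <- function(n_per = 20, sep = 10, sd = 0.5, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per, 0, sd), ncol = 2),
             matrix(rnorm(2 * n_per, sep, sd), ncol = 2))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}
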