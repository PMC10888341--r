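# LS-SVM: kernel, dual system, limiting behaviour, closed-form equivalence,
# one-vs-rest reduction and grid tuning.

test_that("RBF kernel has unit diagonal, symmetry and hand-computed entries", {
  set.seed(1)
  A <- matrix(rnorm(15), ncol = 3)
  K <- rbf_kernel(A, sigma2 = 0.7)
  expect_equal(diag(K), rep(1, 5))
  expect_equal(K, t(K))
  a <- c(1, 0); b <- c(0, 2)
  expect_equal(rbf_kernel(rbind(a), rbind(b), sigma2 = 2)[1, 1],
               exp(-5 / 4))
  # monotone decay with distance
  x0 <- rbind(c(0, 0))
  ds <- seq(0, 6, by = 0.5)
  vals <- vapply(ds, function(d)
    rbf_kernel(x0, rbind(c(d, 0)), sigma2 = 1)[1, 1], numeric(1))
  expect_true(all(diff(vals) < 0 | ds[-1] == 0))
  expect_lt(vals[length(vals)], 1e-7)
  expect_error(rbf_kernel(A, A, sigma2 = 0), "positive")
})

test_that("dual solution satisfies its linear system and sum(alpha) = 0", {
  set.seed(5)
  X <- matrix(rnorm(60), ncol = 3)
  y <- rnorm(20)
  m <- fit_lssvm(X, y, gamma = 10, sigma2 = 0.5, task = "regression")
  expect_lt(abs(sum(m$alpha)), 1e-8)
  K <- rbf_kernel(X, X, sigma2 = 0.5)
  resid <- (K + diag(20) / 10) %*% m$alpha + m$bias - y
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("gamma -> Inf interpolates the training targets", {
  set.seed(6)
  X <- matrix(runif(30), ncol = 2)
  y <- sin(3 * X[, 1]) + X[, 2]
  # a local kernel keeps K well conditioned, so alpha/gamma stays negligible
  m <- fit_lssvm(X, y, gamma = 1e12, sigma2 = 0.05, task = "regression")
  expect_lt(max(abs(predict_lssvm(m, X) - y)), 1e-6)
})

test_that("predictions equal the kernel-ridge closed form", {
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(60), ncol = 3)
    y <- rnorm(20)
    Xn <- matrix(rnorm(24), ncol = 3)
    g <- 10^runif(1, -1, 2); s2 <- 10^runif(1, -1, 1)
    m <- fit_lssvm(X, y, gamma = g, sigma2 = s2, task = "regression")
    expect_equal(predict_lssvm(m, Xn),
                 kernel_ridge_oracle(X, y, Xn, g, s2), tolerance = 1e-8)
  }
})

test_that("decision values vary smoothly with the input", {
  set.seed(8)
  X <- matrix(rnorm(40), ncol = 2)
  y <- rnorm(20)
  m <- fit_lssvm(X, y, gamma = 100, sigma2 = 1, task = "regression")
  x0 <- matrix(c(0.2, -0.1), 1)
  # RBF with sigma2 = 1 is Lipschitz with constant ||alpha||_1 / sqrt(e)
  L <- sum(abs(m$alpha)) * exp(-0.5)
  for (h in c(1e-3, 1e-2)) {
    delta <- abs(predict_lssvm(m, x0 + c(h, 0)) - predict_lssvm(m, x0))
    expect_lt(delta, L * h + 1e-12)
  }
})

test_that("binary labels are recovered exactly on separable data", {
  tc <- make_two_clusters(sep = 6, seed = 10)
  m <- fit_lssvm(tc$X, tc$y, gamma = 100, sigma2 = 1,
                 task = "classification")
  expect_equal(predict_lssvm(m, tc$X), tc$y)
  # training point under near-interpolating gamma returns its own target
  mi <- fit_lssvm(tc$X, tc$y, gamma = 1e10, sigma2 = 1,
                  task = "classification")
  dec <- predict_lssvm(mi, tc$X, type = "decision")
  enc <- ifelse(tc$y == "a", 1, -1)
  expect_lt(max(abs(dec[, "a"] - enc)), 1e-4)
})

test_that("one-vs-rest with two classes reduces to the binary machine", {
  tc <- make_two_clusters(sep = 4, seed = 11)
  m <- fit_lssvm(tc$X, tc$y, gamma = 50, sigma2 = 2,
                 task = "classification")
  dec <- predict_lssvm(m, tc$X, type = "decision")
  # the two one-vs-rest machines are exact negations
  expect_equal(dec[, "a"], -dec[, "b"], tolerance = 1e-10)
  expect_equal(predict_lssvm(m, tc$X),
               ifelse(dec[, "a"] > 0, "a", "b"))
})

test_that("grid tuning is deterministic, honours single-point grids and
           prefers the well-specified bandwidth on smooth data", {
  set.seed(13)
  X <- matrix(runif(80), ncol = 2)
  y <- 2 * X[, 1] - X[, 2]
  one <- hyperparameter_grid(gamma_values = 7, sigma2_values = 0.3,
                             cv_folds = 4, seed = 1)
  sel <- tune_lssvm(X, y, one, task = "regression")
  expect_equal(sel$gamma, 7)
  expect_equal(sel$sigma2, 0.3)

  grid <- hyperparameter_grid(gamma_values = c(1, 100),
                              sigma2_values = c(1e-6, 1, 100),
                              cv_folds = 5, seed = 2)
  sel1 <- tune_lssvm(X, y, grid, task = "regression")
  sel2 <- tune_lssvm(X, y, grid, task = "regression")
  expect_identical(sel1[c("gamma", "sigma2")], sel2[c("gamma", "sigma2")])
  # the selected pair beats the spiky mis-specified bandwidth
  expect_lt(sel1$cv_score, sel1$scores[, "1e-06"][1])
  expect_false(sel1$sigma2 == 1e-6)
})

test_that("classification tuning with stratified folds picks a working model", {
  tc <- make_two_clusters(n_per = 15, sep = 5, seed = 14)
  grid <- hyperparameter_grid(gamma_values = c(0.1, 10),
                              sigma2_values = c(0.1, 10),
                              cv_folds = 5, seed = 3)
  sel <- tune_lssvm(tc$X, tc$y, grid, task = "classification")
  expect_equal(sel$cv_score, 0)
  m <- fit_lssvm(tc$X, tc$y, sel$gamma, sel$sigma2, "classification")
  expect_equal(predict_lssvm(m, tc$X), tc$y)
})

test_that("models serialize to JSON and back losslessly", {
  tc <- make_two_clusters(seed = 15)
  path <- withr::local_tempfile(fileext = ".json")

  m <- fit_lssvm(tc$X, tc$y, gamma = 3, sigma2 = 0.9,
                 task = "classification")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(unclass(m2)[c("alpha", "bias", "gamma", "sigma2", "labels")],
               unclass(m)[c("alpha", "bias", "gamma", "sigma2", "labels")],
               tolerance = 1e-15)
  Xq <- matrix(rnorm(10), ncol = 2)
  expect_identical(predict_lssvm(m2, Xq), predict_lssvm(m, Xq))

  lda <- fit_lda(tc$X, tc$y)
  write_model(lda, path)
  expect_identical(predict_lda(read_model(path), Xq),
                   predict_lda(lda, Xq))

  mlr <- fit_mlr(tc$X, rnorm(nrow(tc$X)))
  write_model(mlr, path)
  expect_equal(predict_mlr(read_model(path), Xq), predict_mlr(mlr, Xq))
})
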