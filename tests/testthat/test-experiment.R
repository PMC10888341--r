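# End-to-end experiments and report rendering. Small grids and few
# permutations keep these runs light; the scientific recovery claims are
# exercised at full strength in the acceptance suite.

small_grid <- function(seed = 1) {
  hyperparameter_grid(gamma_values = c(1, 100),
                      sigma2_values = c(0.01, 1),
                      cv_folds = 4, seed = seed)
}

test_that("configuration rejects incompatible model/task pairs", {
  expect_error(experiment_config("regression", "lda"), "classifier")
  expect_error(experiment_config("binary", "mlr"), "regression model")
  cfg <- experiment_config("binary", "lda", seed = 3)
  expect_equal(cfg$synth$seed, 3L)
})

test_that("binary experiment is deterministic and never fits on test rows", {
  cfg <- experiment_config("binary", "lssvm", seed = 5,
                           grid = small_grid(5), n_permutations = 2)
  r1 <- run_binary(cfg)
  r2 <- run_binary(cfg)
  expect_identical(render_report(r1, "csv"), render_report(r2, "csv"))
  expect_length(intersect(r1$audit$fit_rows, r1$split$test), 0L)
  expect_named(r1$reports, c("calibration", "y_randomization", "test"))
  # low-noise LS-SVM separates pure from blended essentially perfectly
  expect_gt(r1$reports$test$overall[["MCC"]], 0.9)
})

test_that("multiclass experiment reports all six classes one-vs-rest", {
  cfg <- experiment_config("multiclass", "lssvm", seed = 6,
                           grid = small_grid(6), n_permutations = 2)
  res <- run_multiclass(cfg)
  expect_equal(res$reports$test$per_class$label,
               c("pure", "canola", "sunflower", "corn", "olive", "soybean"))
  expect_equal(res$reports$calibration$overall,
               colMeans(as.matrix(
                 res$reports$calibration$per_class[, -1])))
  # permutation-null MCC collapses far below the genuine-model MCC (~1)
  expect_lt(abs(res$reports$y_randomization$overall[["MCC"]]), 0.4)
  expect_gt(res$reports$test$overall[["MCC"]], 0.8)
})

test_that("perfect-separation fixture gives MCC 1 for every class", {
  # near-noiseless data keeps replicate points distinct (so every class
  # reaches the test set) while classes stay cleanly separated
  cfg0 <- synthetic_config(noise_sd = 1e-4, seed = 1)
  ds <- generate_classification_dataset(cfg0)
  g <- hyperparameter_grid(gamma_values = 10^(2:6),
                           sigma2_values = 10^(-6:-3),
                           cv_folds = 4, seed = 1)
  cfg <- experiment_config("multiclass", "lssvm", seed = 1, data = ds,
                           grid = g, n_permutations = 1)
  res <- run_multiclass(cfg)
  expect_true(all(res$reports$test$per_class$MCC == 1))
  expect_true(all(res$reports$calibration$per_class$MCC == 1))
})

test_that("noiseless linear regression with MLR is exact; Rm2 <= R2 always", {
  cfg <- experiment_config("regression", "mlr", seed = 2,
                           synth = synthetic_config(noise_sd = 0,
                                                    nonlinearity = 0,
                                                    seed = 2),
                           n_permutations = 2)
  res <- run_regression(cfg, "sunflower")
  expect_lt(res$reports$test[["RMSE"]], 1e-8)
  expect_equal(res$reports$test[["R2"]], 1)
  for (seed in 1:3) {
    r <- run_regression(experiment_config("regression", "mlr", seed = seed,
                                          n_permutations = 2), "olive")
    expect_lte(r$reports$test[["Rm2"]], r$reports$test[["R2"]] + 1e-12)
    expect_length(intersect(r$audit$fit_rows, r$split$test), 0L)
  }
})

test_that("regression stages carry the table-shaped statistics", {
  cfg <- experiment_config("regression", "lssvm", seed = 4,
                           grid = small_grid(4), n_permutations = 3)
  res <- run_regression(cfg, "canola")
  expect_named(res$reports$calibration, c("RMSE", "R2"))
  expect_named(res$reports$y_randomization, c("RMSE", "R2", "cRp2"))
  expect_named(res$reports$test, c("RMSE", "R2", "R0_2", "Rm2"))
  expect_gte(res$reports$y_randomization[["cRp2"]], 0)
})

test_that("rendered reports are deterministic and table-shaped", {
  cfg <- experiment_config("binary", "lda", seed = 7, n_permutations = 2)
  res <- run_binary(cfg)
  txt1 <- render_report(res, "text")
  txt2 <- render_report(res, "text")
  expect_identical(txt1, txt2)
  csv <- render_report(res, "csv")
  expect_equal(csv[1], "stage,metric,Overall,Pure,Blended")
  expect_length(csv, 1 + 3 * 6)  # 3 stages x 6 metrics
  # percent metrics to 1 decimal, ratio metrics to 2
  expect_match(csv[2], "^calibration,PRE,\\d+\\.\\d(,\\d+\\.\\d){2}$")
  expect_match(csv[grep(",F1S,", csv)[1]], "0\\.\\d\\d|1\\.00")

  reg <- run_regression(experiment_config("regression", "mlr", seed = 7,
                                          n_permutations = 2), "soybean")
  lines <- render_report(reg, "csv")
  expect_equal(lines[1], "stage,metric,value")
  expect_equal(sum(grepl("^test,", lines)), 3L)  # RMSE, R2, Rm2
  path <- withr::local_tempfile(fileext = ".csv")
  render_report(reg, "csv", path = path)
  expect_identical(readLines(path), lines)
})
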