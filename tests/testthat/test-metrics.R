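# Confusion accounting, percent metrics, MCC, macro reports, and the
# regression validation statistics.

test_that("confusion counting is one-vs-rest and total-preserving", {
  y <- rep(c("blended", "pure"), c(41, 9))
  cc <- confusion_counts(y, y, "blended")
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 41, TN = 9, FP = 0, FN = 0))
  cc2 <- confusion_counts(y, rep("blended", 50), "blended")
  expect_equal(unlist(cc2[c("TP", "TN", "FP", "FN")]),
               c(TP = 41, TN = 0, FP = 9, FN = 0))
  expect_error(confusion_counts(character(), character(), "x"), "empty")
  expect_error(confusion_counts(y, y[-1], "blended"), "lengths differ")
})

test_that("degenerate all-positive prediction reproduces the known row", {
  m <- class_metrics(list(TP = 41, TN = 0, FP = 9, FN = 0))
  expect_equal(m[["PRE"]], 82)
  expect_equal(m[["REC"]], 100)
  expect_equal(m[["ACU"]], 82)
  expect_equal(m[["ERR"]], 18)
  expect_equal(round(m[["F1S"]], 2), 0.90)
  expect_equal(m[["MCC"]], 0)
})

test_that("perfect prediction scores 100 / 1.00 everywhere", {
  m <- class_metrics(list(TP = 41, TN = 9, FP = 0, FN = 0))
  expect_equal(unname(m), c(100, 100, 100, 0, 1, 1))
})

test_that("metrics agree with the vector-counting oracle over small totals", {
  for (total in 1:8) {
    combos <- expand.grid(tp = 0:total, tn = 0:total, fp = 0:total)
    for (i in seq_len(nrow(combos))) {
      tp <- combos$tp[i]; tn <- combos$tn[i]; fp <- combos$fp[i]
      fn <- total - tp - tn - fp
      if (fn < 0) next
      expect_equal(class_metrics(list(TP = tp, TN = tn, FP = fp, FN = fn)),
                   metrics_from_vectors_oracle(tp, tn, fp, fn),
                   tolerance = 1e-12)
    }
  }
  expect_error(class_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "total")
})

test_that("macro report averages per-class rows and validates labels", {
  y_true <- rep(c("blended", "pure"), c(41, 9))
  rep1 <- classification_report(y_true, rep("blended", 50),
                                labels = c("pure", "blended"))
  expect_equal(rep1$overall[["PRE"]], 41)
  expect_equal(rep1$overall[["REC"]], 50)
  expect_equal(rep1$overall,
               colMeans(as.matrix(rep1$per_class[, -1])))
  expect_error(classification_report(y_true, rep("olive", 50),
                                     labels = c("pure", "blended")),
               "not covered")
  # perfect multiclass
  y6 <- rep(c("a", "b", "c"), each = 4)
  rep2 <- classification_report(y6, y6)
  expect_true(all(rep2$per_class$ACU == 100))
  expect_true(all(rep2$per_class$MCC == 1))
})

test_that("binary per-class ACU, ERR and MCC coincide across the classes", {
  set.seed(77)
  for (i in 1:20) {
    y_true <- sample(c("pure", "blended"), 30, replace = TRUE,
                     prob = c(0.3, 0.7))
    y_pred <- sample(c("pure", "blended"), 30, replace = TRUE)
    if (length(unique(y_true)) < 2) next
    r <- classification_report(y_true, y_pred,
                               labels = c("pure", "blended"))
    expect_equal(r$per_class$ACU[1], r$per_class$ACU[2])
    expect_equal(r$per_class$ERR[1], r$per_class$ERR[2])
    expect_equal(r$per_class$MCC[1], r$per_class$MCC[2])
  }
})

test_that("rmse and r_squared match their definitions", {
  a <- c(1, 2, 3, 4); p <- c(1.5, 1.5, 3.5, 3.5)
  expect_equal(rmse(a, a), 0)
  expect_equal(r_squared(a, 2 * a + 1), 1)
  expect_equal(rmse(a, p), sqrt(mean((a - p)^2)))
  expect_equal(r_squared(a, p), cor(a, p)^2)
  expect_equal(rmse(a, rep(2.5, 4)), sqrt(mean((a - 2.5)^2)))
  expect_error(r_squared(a, rep(2.5, 4)), "constant")
  expect_error(r_squared(rep(1, 4), a), "zero variance")
})

test_that("through-origin R0 equals 1 for proportional data, < R2 otherwise", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(r0_squared(a, a), 1)
  expect_equal(r0_squared(a, 2 * a), 1)
  p <- a + 10  # large intercept
  expect_lt(r0_squared(a, p), r_squared(a, p))
  set.seed(3)
  p2 <- 1.2 * a + 4 + rnorm(5, sd = 0.1)
  k <- sum(a * p2) / sum(a^2)
  expect_equal(r0_squared(a, p2),
               1 - sum((p2 - k * a)^2) / sum((p2 - mean(p2))^2))
})

test_that("Rm2 penalizes the origin gap and clamps negative gaps", {
  expect_equal(rm_squared(0.9, 0.9), 0.9)
  expect_equal(rm_squared(1, 1), 1)
  expect_equal(rm_squared(0.97, 0.95), 0.97 * (1 - sqrt(0.02)))
  expect_equal(rm_squared(0.8, 0.9), 0.8)  # clamped gap
  # Rm2 = R2 exactly when the two fits coincide
  a <- 1:6; expect_equal(rm_squared(r_squared(a, 3 * a),
                                    r0_squared(a, 3 * a)), 1)
})

test_that("cRp2 contrasts calibration against randomization", {
  expect_equal(round(as.numeric(crp_squared(0.99, 0.64)), 2), 0.59)
  expect_equal(round(as.numeric(crp_squared(0.96, 0.06)), 2), 0.93)
  expect_equal(as.numeric(crp_squared(0.9, 0)), 0.9)
  clamped <- crp_squared(0.5, 0.9)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
})
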