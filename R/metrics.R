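# Classification and regression validation statistics: confusion accounting,
# precision / recall / accuracy / error rate / F1 / Matthews correlation
# (percent metrics on the 0-100 scale), RMSE, R-squared, the through-origin
# R0-squared, Rm-squared and the randomization statistic cRp-squared.

#' One-vs-rest confusion counts
#'
#' @param y_true,y_pred Equal-length nonempty label vectors.
#' @param positive_label The label treated as positive.
#' @return Object of class `confusion_counts`: list with integer `TP`, `TN`,
#'   `FP`, `FN` summing to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_label) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  tp <- y_true == positive_label
  pp <- y_pred == positive_label
  structure(list(TP = sum(tp & pp), TN = sum(!tp & !pp),
                 FP = sum(!tp & pp), FN = sum(tp & !pp)),
            class = "confusion_counts")
}

#' Per-class metrics from confusion counts
#'
#' Precision, recall, accuracy and error rate on the percent scale; F1-score
#' in `[0, 1]`; Matthews correlation coefficient in `[-1, 1]`. Degenerate
#' denominators follow the reporting conventions of the food-authentication
#' tables this package emulates: PRE = 0 when `TP + FP = 0`, REC = 0 when
#' `TP + FN = 0`, F1S = 0 when `2TP + FP + FN = 0`, and MCC = 0 when any of
#' the four marginal factors is 0. `ACU + ERR = 100` exactly.
#'
#' @param counts A [confusion_counts()] object (or list with TP, TN, FP,
#'   FN).
#' @return Named numeric vector `c(PRE, REC, ACU, ERR, F1S, MCC)`.
#' @export
class_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  if (total <= 0) stop("confusion total must be > 0", call. = FALSE)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp) * 100
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn) * 100
  acu <- (tp + tn) / total * 100
  err <- 100 - acu
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(PRE = pre, REC = rec, ACU = acu, ERR = err, F1S = f1, MCC = mcc)
}

metric_names <- function() c("PRE", "REC", "ACU", "ERR", "F1S", "MCC")

#' Full classification report
#'
#' One-vs-rest [class_metrics()] for every label plus an "overall" row equal
#' to the field-wise unweighted (macro) average of the per-class rows — the
#' convention under which an all-majority binary prediction on an 82 %
#' majority gives overall precision 41.0 and overall recall 50.0.
#'
#' @param y_true,y_pred Label vectors; every predicted label must appear in
#'   `labels`.
#' @param labels Class labels in reporting order; defaults to the sorted
#'   classes observed in `y_true`.
#' @param stage One of `"calibration"`, `"y_randomization"`, `"test"`.
#' @return Object of class `classification_report`: list with `per_class`
#'   (data frame, one row per label), `overall` (named numeric) and `stage`.
#' @export
classification_report <- function(y_true, y_pred, labels = NULL,
                                  stage = "test") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  labels <- labels %||% sort(unique(y_true))
  unseen <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(unseen) > 0L)
    stop("label(s) not covered by `labels`: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  per <- t(vapply(labels,
                  function(l) class_metrics(confusion_counts(y_true, y_pred, l)),
                  numeric(6)))
  per_df <- data.frame(label = labels, per, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(list(per_class = per_df, overall = colMeans(per), stage = stage),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 1, ...) {
  cat(sprintf("<classification_report> stage=%s\n", x$stage))
  full <- rbind(Overall = x$overall,
                as.matrix(x$per_class[, metric_names()]))
  rownames(full) <- c("Overall", x$per_class$label)
  print(round(full, 2))
  invisible(x)
}

#' Root mean squared error
#'
#' @param actual,predicted Equal-length nonempty numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) == 0L)
    stop("inputs must be nonempty and of equal length", call. = FALSE)
  sqrt(mean((actual - predicted)^2))
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between actual and predicted values.
#'
#' @inheritParams rmse
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) == 0L)
    stop("inputs must be nonempty and of equal length", call. = FALSE)
  if (stats::var(actual) == 0)
    stop("R-squared undefined: actual values have zero variance",
         call. = FALSE)
  if (stats::var(predicted) == 0)
    stop("R-squared undefined: predicted values are constant",
         call. = FALSE)
  cor(actual, predicted)^2
}

#' Through-origin coefficient of determination
#'
#' R0-squared from the least-squares fit of predicted on actual constrained
#' through the origin: `1 - sum((p - k a)^2) / sum((p - mean(p))^2)` with
#' `k = sum(a p) / sum(a^2)`. Equals R-squared when the free fit already
#' passes through the origin.
#'
#' @inheritParams rmse
#' @return R0-squared (can be negative for strongly offset data).
#' @export
r0_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) == 0L)
    stop("inputs must be nonempty and of equal length", call. = FALSE)
  if (sum(actual^2) == 0)
    stop("R0-squared undefined: actual values all zero", call. = FALSE)
  ss_tot <- sum((predicted - mean(predicted))^2)
  if (ss_tot == 0)
    stop("R0-squared undefined: predicted values are constant",
         call. = FALSE)
  k <- sum(actual * predicted) / sum(actual^2)
  1 - sum((predicted - k * actual)^2) / ss_tot
}

#' Rm-squared external-validation statistic
#'
#' `Rm2 = R2 * (1 - sqrt(R2 - R02))`, penalizing divergence between the free
#' and the through-origin fit of predicted versus actual values; values
#' above 0.5 are conventionally taken as evidence of congruent predictions.
#' A negative gap (R02 > R2) is clamped to zero, giving `Rm2 = R2`.
#'
#' @param R2 Free-fit R-squared.
#' @param R0_2 Through-origin R-squared.
#' @return Rm-squared.
#' @export
rm_squared <- function(R2, R0_2) {
  R2 * (1 - sqrt(max(R2 - R0_2, 0)))
}

#' cRp-squared randomization statistic
#'
#' `cRp2 = sqrt(Rcal2 * (Rcal2 - Rrand2))`, contrasting the calibration
#' R-squared with the y-randomization R-squared; values above 0.5 attest the
#' absence of chance correlation. A negative radicand (randomized models
#' outperforming the real one) is clamped to 0 and flagged via the
#' `"clamped"` attribute.
#'
#' @param Rcal2 Calibration R-squared.
#' @param Rrand2 Mean y-randomization R-squared.
#' @return cRp-squared, with logical attribute `clamped`.
#' @export
crp_squared <- function(Rcal2, Rrand2) {
  rad <- Rcal2 * (Rcal2 - Rrand2)
  structure(sqrt(max(rad, 0)), clamped = rad < 0)
}
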