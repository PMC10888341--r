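# End-to-end experiments: binary classification (pure vs blended),
# six-class classification (pure + five adulterants) and per-oil blend
# quantification, each with calibration, y-randomization and test stages,
# rendered as the stage x class report tables customary in
# food-authentication studies.

#' Experiment configuration
#'
#' @param task `"binary"`, `"multiclass"` or `"regression"`.
#' @param model `"lda"` or `"lssvm"` for classification; `"mlr"` or
#'   `"lssvm"` for regression.
#' @param illuminant `"white"` or `"uv"`.
#' @param split_fraction Kennard-Stone calibration share (default 0.7).
#' @param calibration_size Optional explicit calibration count.
#' @param grid [hyperparameter_grid()] for LS-SVM tuning; defaults to
#'   [default_grid()] seeded from `seed`.
#' @param n_permutations y-randomization permutations (default 100).
#' @param retune_permutations Re-tune LS-SVM hyperparameters on every
#'   permuted response (default TRUE); FALSE freezes the originally tuned
#'   values.
#' @param seed Integer master seed for data generation, folds and
#'   permutations.
#' @param synth [synthetic_config()] used when no `data` is supplied;
#'   defaults to the standard profile seeded from `seed`.
#' @param data Optional [oil_dataset()]; when NULL the synthetic generator
#'   supplies the data.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("binary", "multiclass", "regression"),
                              model = c("lssvm", "lda", "mlr"),
                              illuminant = "white",
                              split_fraction = 0.7,
                              calibration_size = NULL,
                              grid = NULL,
                              n_permutations = 100L,
                              retune_permutations = TRUE,
                              seed = 1L,
                              synth = NULL,
                              data = NULL) {
  task <- match.arg(task)
  model <- match.arg(model)
  check_illuminant(illuminant)
  if (task == "regression" && model == "lda")
    stop("LDA is a classifier; use 'mlr' or 'lssvm' for regression",
         call. = FALSE)
  if (task != "regression" && model == "mlr")
    stop("MLR is a regression model; use 'lda' or 'lssvm' for classification",
         call. = FALSE)
  seed <- as.integer(seed)
  structure(
    list(task = task, model = model, illuminant = illuminant,
         split_fraction = split_fraction,
         calibration_size = calibration_size,
         grid = grid %||% default_grid(seed = seed),
         n_permutations = as.integer(n_permutations),
         retune_permutations = isTRUE(retune_permutations),
         seed = seed,
         synth = synth %||% synthetic_config(seed = seed),
         data = data),
    class = "experiment_config"
  )
}

# Fit a classifier according to the configured model; returns the fitted
# model, a prediction closure, and tuned hyperparameters (LS-SVM only).
fit_classifier <- function(model, X, y, grid) {
  if (model == "lda") {
    m <- fit_lda(X, y)
    list(model = m, hyper = NULL,
         predict = function(Xn) predict_lda(m, Xn))
  } else {
    tu <- tune_lssvm(X, y, grid = grid, task = "classification")
    m <- fit_lssvm(X, y, gamma = tu$gamma, sigma2 = tu$sigma2,
                   task = "classification")
    list(model = m, hyper = tu,
         predict = function(Xn) predict_lssvm(m, Xn))
  }
}

flatten_report <- function(rep) {
  v <- c(rep$overall,
         unlist(lapply(seq_len(nrow(rep$per_class)), function(i)
           unlist(rep$per_class[i, metric_names()]))))
  names(v) <- c(paste0("overall.", metric_names()),
                as.vector(t(outer(rep$per_class$label, metric_names(),
                                  paste, sep = "."))))
  v
}

unflatten_report <- function(v, labels, stage) {
  per <- t(vapply(labels, function(l) v[paste0(l, ".", metric_names())],
                  numeric(6)))
  colnames(per) <- metric_names()
  structure(list(per_class = data.frame(label = labels, per,
                                        row.names = NULL,
                                        stringsAsFactors = FALSE),
                 overall = v[paste0("overall.", metric_names())] |>
                   stats::setNames(metric_names()),
                 stage = stage),
            class = "classification_report")
}

run_classification <- function(cfg, y_all, labels) {
  ds <- cfg$data %||%
    generate_classification_dataset(cfg$synth, cfg$illuminant)
  y_all <- y_all(ds)
  X <- features_matrix(ds)
  split <- split_dataset(ds, cfg$split_fraction, cfg$calibration_size)
  cal <- split$calibration
  test <- split$test
  Xc <- X[cal, , drop = FALSE]
  yc <- y_all[cal]
  fit <- fit_classifier(cfg$model, Xc, yc, cfg$grid)
  rep_cal <- classification_report(yc, fit$predict(Xc), labels,
                                   stage = "calibration")
  rep_test <- classification_report(y_all[test],
                                    fit$predict(X[test, , drop = FALSE]),
                                    labels, stage = "test")
  frozen <- fit$hyper
  fit_fn <- function(Xp, yp) {
    f <- if (cfg$model == "lssvm" && !cfg$retune_permutations) {
      m <- fit_lssvm(Xp, yp, gamma = frozen$gamma, sigma2 = frozen$sigma2,
                     task = "classification")
      list(predict = function(Xn) predict_lssvm(m, Xn))
    } else {
      fit_classifier(cfg$model, Xp, yp, cfg$grid)
    }
    flatten_report(classification_report(yp, f$predict(Xp), labels,
                                         stage = "y_randomization"))
  }
  yr <- y_randomization(fit_fn, Xc, yc,
                        n_permutations = cfg$n_permutations,
                        seed = cfg$seed)
  rep_yr <- unflatten_report(yr$mean_scores, labels, "y_randomization")
  structure(
    list(config = cfg, data = ds, split = split, model = fit$model,
         hyper = fit$hyper,
         reports = list(calibration = rep_cal, y_randomization = rep_yr,
                        test = rep_test),
         yrand = yr,
         audit = list(fit_rows = sort(cal),
                      test_rows = test),
         warnings = character()),
    class = "experiment_result"
  )
}

#' Run the binary pure-vs-blended experiment
#'
#' Labels derive from the blend fraction (`pure` when 0, `blended`
#' otherwise); the pipeline splits by Kennard-Stone, fits the configured
#' classifier on the calibration set (tuning LS-SVM by cross-validation),
#' runs the y-randomization test on the calibration set only, and scores the
#' untouched test set.
#'
#' @param cfg An [experiment_config()] with task `"binary"`.
#' @return An `experiment_result` with calibration / y-randomization / test
#'   [classification_report()]s.
#' @export
run_binary <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$task != "binary") stop("cfg$task must be 'binary'", call. = FALSE)
  make_y <- function(ds) {
    y <- ifelse(ds$fraction == 0, "pure", "blended")
    if (length(unique(y)) < 2L)
      stop("binary task needs both pure and blended samples", call. = FALSE)
    y
  }
  run_classification(cfg, make_y, labels = c("pure", "blended"))
}

#' Run the six-class experiment
#'
#' Classes are pure avocado oil plus the adulterant identity of each blend
#' (pooled over fractions), reported one-vs-rest per class.
#'
#' @param cfg An [experiment_config()] with task `"multiclass"`.
#' @return An `experiment_result`.
#' @export
run_multiclass <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$task != "multiclass")
    stop("cfg$task must be 'multiclass'", call. = FALSE)
  labels <- c("pure", adulterant_levels())
  make_y <- function(ds) {
    y <- ifelse(ds$fraction == 0, "pure", ds$oil)
    missing <- setdiff(labels, unique(y))
    if (length(missing) > 0L)
      stop("six-class task: missing class(es) ",
           paste(missing, collapse = ", "), call. = FALSE)
    y
  }
  run_classification(cfg, make_y, labels = labels)
}

#' Run a blend-quantification experiment for one adulterant
#'
#' Regresses the blend percentage (0-50) on the colour features: fit on the
#' Kennard-Stone calibration set, y-randomize on the calibration set,
#' evaluate RMSE / R-squared on both splits, Rm-squared on the test set and
#' cRp-squared from the randomization.
#'
#' @param cfg An [experiment_config()] with task `"regression"`.
#' @param adulterant The blended oil (required when `cfg$data` is NULL).
#' @return An `experiment_result` whose `reports` are named numeric vectors:
#'   calibration `(RMSE, R2)`, y_randomization `(RMSE, R2, cRp2)`, test
#'   `(RMSE, R2, R0_2, Rm2)`.
#' @export
run_regression <- function(cfg, adulterant = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$task != "regression")
    stop("cfg$task must be 'regression'", call. = FALSE)
  ds <- cfg$data %||% {
    if (is.null(adulterant))
      stop("`adulterant` is required for synthetic regression data",
           call. = FALSE)
    generate_calibration_dataset(adulterant, cfg$synth, cfg$illuminant)
  }
  if (length(unique(ds$fraction)) < 3L)
    stop("regression needs >= 3 distinct fraction levels", call. = FALSE)
  y_all <- 100 * ds$fraction  # percent blend
  X <- features_matrix(ds)
  split <- split_dataset(ds, cfg$split_fraction, cfg$calibration_size)
  cal <- split$calibration
  test <- split$test
  Xc <- X[cal, , drop = FALSE]
  yc <- y_all[cal]
  if (cfg$model == "mlr") {
    m <- fit_mlr(Xc, yc)
    hyper <- NULL
    pred <- function(Xn) predict_mlr(m, Xn)
  } else {
    hyper <- tune_lssvm(Xc, yc, grid = cfg$grid, task = "regression")
    m <- fit_lssvm(Xc, yc, gamma = hyper$gamma, sigma2 = hyper$sigma2,
                   task = "regression")
    pred <- function(Xn) predict_lssvm(m, Xn)
  }
  p_cal <- pred(Xc)
  p_test <- pred(X[test, , drop = FALSE])
  r2_cal <- r_squared(yc, p_cal)
  rep_cal <- c(RMSE = rmse(yc, p_cal), R2 = r2_cal)
  r2_test <- r_squared(y_all[test], p_test)
  r02_test <- r0_squared(y_all[test], p_test)
  rep_test <- c(RMSE = rmse(y_all[test], p_test), R2 = r2_test,
                R0_2 = r02_test, Rm2 = rm_squared(r2_test, r02_test))
  fit_fn <- function(Xp, yp) {
    mp <- if (cfg$model == "mlr") {
      fit_mlr(Xp, yp)
    } else if (cfg$retune_permutations) {
      tu <- tune_lssvm(Xp, yp, grid = cfg$grid, task = "regression")
      fit_lssvm(Xp, yp, gamma = tu$gamma, sigma2 = tu$sigma2,
                task = "regression")
    } else {
      fit_lssvm(Xp, yp, gamma = hyper$gamma, sigma2 = hyper$sigma2,
                task = "regression")
    }
    pp <- if (cfg$model == "mlr") predict_mlr(mp, Xp)
          else predict_lssvm(mp, Xp)
    # a permuted model predicting a constant carries no correlation
    r2p <- tryCatch(r_squared(yp, pp), error = function(e) 0)
    c(RMSE = rmse(yp, pp), R2 = r2p)
  }
  yr <- y_randomization(fit_fn, Xc, yc,
                        n_permutations = cfg$n_permutations,
                        seed = cfg$seed)
  crp <- crp_squared(r2_cal, unname(yr$mean_scores["R2"]))
  rep_yr <- c(yr$mean_scores, cRp2 = as.numeric(crp))
  structure(
    list(config = cfg, data = ds, split = split, model = m, hyper = hyper,
         adulterant = attr(ds, "provenance")$adulterant %||% adulterant,
         reports = list(calibration = rep_cal, y_randomization = rep_yr,
                        test = rep_test),
         yrand = yr,
         audit = list(fit_rows = sort(cal), test_rows = test),
         warnings = if (isTRUE(attr(crp, "clamped")))
           "cRp2 radicand clamped to 0" else character()),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> task=%s model=%s illuminant=%s seed=%d\n",
              x$config$task, x$config$model, x$config$illuminant,
              x$config$seed))
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

cap_label <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

fmt_metric <- function(metric, value) {
  if (metric %in% c("PRE", "REC", "ACU", "ERR")) sprintf("%.1f", value)
  else sprintf("%.2f", value)
}

#' Render an experiment report
#'
#' Produces the stage x metric x class grid used in oil-authentication
#' reports: percent metrics to one decimal, unit-ratio metrics to two.
#' Output is deterministic for a fixed result.
#'
#' @param res An `experiment_result`.
#' @param format `"text"` (aligned table) or `"csv"`.
#' @param path Optional file to write the lines to.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
render_report <- function(res, format = c("text", "csv"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(res, "experiment_result"))
  stages <- c("calibration", "y_randomization", "test")
  stage_disp <- c(calibration = "calibration", y_randomization = "y-rand.",
                  test = "test")
  if (res$config$task == "regression") {
    shown <- list(calibration = c("RMSE", "R2"),
                  y_randomization = c("RMSE", "R2", "cRp2"),
                  test = c("RMSE", "R2", "Rm2"))
    cells <- do.call(rbind, lapply(stages, function(st) {
      v <- res$reports[[st]]
      data.frame(stage = stage_disp[[st]], metric = shown[[st]],
                 value = sprintf("%.2f", v[shown[[st]]]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    labels <- res$reports$calibration$per_class$label
    cells <- do.call(rbind, lapply(stages, function(st) {
      rep <- res$reports[[st]]
      rows <- lapply(metric_names(), function(mn) {
        vals <- c(rep$overall[[mn]],
                  rep$per_class[[mn]])
        out <- as.list(vapply(vals, function(v) fmt_metric(mn, v),
                              character(1)))
        names(out) <- c("Overall", cap_label(labels))
        c(list(stage = stage_disp[[st]], metric = mn), out)
      })
      do.call(rbind, lapply(rows, as.data.frame,
                            stringsAsFactors = FALSE, check.names = FALSE))
    }))
  }
  if (format == "csv") {
    lines <- c(paste(names(cells), collapse = ","),
               apply(cells, 1L, paste, collapse = ","))
  } else {
    m <- rbind(names(cells), as.matrix(cells))
    widths <- apply(nchar(m), 2L, max)
    lines <- apply(m, 1L, function(row)
      paste(mapply(formatC, row, width = widths, flag = "-"),
            collapse = "  "))
    lines <- trimws(lines, which = "right")
  }
  lines <- unname(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
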