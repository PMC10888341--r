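# Raw sensor ingest: parsing logged RGBC quadruples, averaging repeated
# readings, clear-channel normalization, and the dataset interchange CSV.

#' Construct a raw sensor reading
#'
#' One (possibly averaged) RGBC acquisition. Channel values are kept
#' real-valued; integration time and gain are carried as metadata only.
#'
#' @param R,G,B,C Nonnegative channel counts.
#' @param illuminant `"white"` or `"uv"`.
#' @param integration_ms Positive integration time in milliseconds
#'   (default 24).
#' @param gain Positive sensor gain (default 1).
#' @return Object of class `raw_reading`.
#' @export
raw_reading <- function(R, G, B, C, illuminant = "white",
                        integration_ms = 24, gain = 1) {
  check_illuminant(illuminant)
  ch <- c(R = R, G = G, B = B, C = C)
  if (any(!is.finite(ch)) || any(ch < 0))
    stop("channel counts must be finite and >= 0", call. = FALSE)
  if (integration_ms <= 0 || gain <= 0)
    stop("`integration_ms` and `gain` must be positive", call. = FALSE)
  structure(list(R = unname(R), G = unname(G), B = unname(B), C = unname(C),
                 illuminant = illuminant,
                 integration_ms = integration_ms, gain = gain),
            class = "raw_reading")
}

#' @export
print.raw_reading <- function(x, ...) {
  cat(sprintf("<raw_reading %s> R=%.6g G=%.6g B=%.6g C=%.6g\n",
              x$illuminant, x$R, x$G, x$B, x$C))
  invisible(x)
}

#' Parse a raw sensor log
#'
#' Each non-blank line must hold four comma-separated nonnegative integers
#' `R,G,B,C`, the format produced by logging the sensor's serial output.
#'
#' @param lines Character vector of log lines, or a connection / file path
#'   readable by [readLines()].
#' @param illuminant Illuminant tag attached to every reading.
#' @return List of [raw_reading()] objects, in input order.
#' @export
parse_sensor_log <- function(lines, illuminant = "white") {
  check_illuminant(illuminant)
  if (!is.character(lines)) lines <- readLines(lines)
  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    fields <- trimws(strsplit(line, ",", fixed = TRUE)[[1L]])
    if (length(fields) != 4L)
      stop(sprintf("line %d: expected 4 comma-separated values, got %d",
                   i, length(fields)), call. = FALSE)
    if (!all(grepl("^[0-9]+$", fields)))
      stop(sprintf("line %d: channels must be nonnegative integers ('%s')",
                   i, line), call. = FALSE)
    vals <- as.numeric(fields)
    out[[length(out) + 1L]] <-
      raw_reading(vals[1L], vals[2L], vals[3L], vals[4L],
                  illuminant = illuminant)
  }
  out
}

#' Average repeated sensor readings
#'
#' Channel-wise arithmetic mean of a list of readings taken under the same
#' illuminant; metadata of the first reading is propagated. Mirrors the
#' standard acquisition protocol of averaging 10 single readings.
#'
#' @param readings Nonempty list of [raw_reading()] objects.
#' @return One [raw_reading()] with real-valued averaged channels.
#' @export
average_readings <- function(readings) {
  if (!is.list(readings) || length(readings) == 0L)
    stop("`readings` must be a nonempty list of raw readings", call. = FALSE)
  if (!all(vapply(readings, inherits, logical(1), "raw_reading")))
    stop("all elements must be raw_reading objects", call. = FALSE)
  illums <- unique(vapply(readings, `[[`, character(1), "illuminant"))
  if (length(illums) != 1L)
    stop("cannot average readings taken under different illuminants",
         call. = FALSE)
  ch <- vapply(readings, function(x) c(x$R, x$G, x$B, x$C), numeric(4))
  m <- rowMeans(ch)
  first <- readings[[1L]]
  raw_reading(m[1L], m[2L], m[3L], m[4L], illuminant = illums,
              integration_ms = first$integration_ms, gain = first$gain)
}

#' Clear-channel normalization
#'
#' Divides the raw R, G, B counts by the clear-channel count C, yielding the
#' dimensionless (r, g, b) descriptors used by all models. Invariant to
#' rescaling all four channels by a common positive factor.
#'
#' @param raw A [raw_reading()] with `C > 0`.
#' @param bound Permissive upper bound on each ratio (default 2) used to
#'   catch corrupt input; physical readings have ratios <= 1.
#' @return Named numeric vector `c(r, g, b)`.
#' @export
normalize_reading <- function(raw, bound = 2) {
  stopifnot(inherits(raw, "raw_reading"))
  if (raw$C <= 0)
    stop("degenerate reading: C must be > 0 for normalization",
         call. = FALSE)
  feat <- c(r = raw$R / raw$C, g = raw$G / raw$C, b = raw$B / raw$C)
  if (any(!is.finite(feat)) || any(feat < 0) || any(feat > bound))
    stop("normalized features outside [0, ", bound,
         "]: corrupt reading?", call. = FALSE)
  feat
}

dataset_columns <- function() {
  c("sample_id", "oil", "fraction", "replicate", "illuminant",
    "R", "G", "B", "C", "r", "g", "b")
}

#' Construct an oil-sample dataset
#'
#' The central container: one row per specimen with its identity (oil,
#' fraction, replicate), illuminant, averaged raw counts and C-normalized
#' features. Validity rules: nonempty; a single illuminant throughout; oils
#' and illuminants from the admissible vocabularies; fractions in
#' `[0, 0.5]` with fraction 0 if and only if the oil is avocado; stored
#' features consistent with `R/C, G/C, B/C`; for task `"regression"` a
#' single adulterant oil.
#'
#' @param df Data frame with the columns listed in [read_dataset()].
#' @param task One of `"classification"`, `"regression"`.
#' @param provenance Free-form list recording at least the data source and,
#'   for synthetic data, the seed.
#' @return Object of classes `oil_dataset` and `data.frame`.
#' @export
oil_dataset <- function(df, task = c("classification", "regression"),
                        provenance = list()) {
  task <- match.arg(task)
  missing_cols <- setdiff(dataset_columns(), names(df))
  if (length(missing_cols) > 0L)
    stop("missing dataset column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, dataset_columns()]
  if (nrow(df) == 0L) stop("dataset must be nonempty", call. = FALSE)
  bad_oil <- which(!(df$oil %in% oil_levels()))
  if (length(bad_oil) > 0L)
    stop("row ", bad_oil[1L], ": unknown oil '", df$oil[bad_oil[1L]], "'",
         call. = FALSE)
  bad_ill <- which(!(df$illuminant %in% illuminant_levels()))
  if (length(bad_ill) > 0L)
    stop("row ", bad_ill[1L], ": unknown illuminant '",
         df$illuminant[bad_ill[1L]], "'", call. = FALSE)
  if (length(unique(df$illuminant)) != 1L)
    stop("all samples in a dataset must share one illuminant", call. = FALSE)
  bad_f <- which(!is.finite(df$fraction) | df$fraction < 0 | df$fraction > 0.5)
  if (length(bad_f) > 0L)
    stop("row ", bad_f[1L], ": fraction ", df$fraction[bad_f[1L]],
         " outside [0, 0.5]", call. = FALSE)
  bad_pure <- which((df$fraction == 0) != (df$oil == "avocado"))
  if (length(bad_pure) > 0L)
    stop("row ", bad_pure[1L],
         ": fraction 0 if and only if the oil is avocado", call. = FALSE)
  feat <- cbind(df$R, df$G, df$B) / df$C
  stored <- cbind(df$r, df$g, df$b)
  if (max(abs(feat - stored)) > 1e-6)
    stop("stored (r, g, b) features disagree with R/C, G/C, B/C",
         call. = FALSE)
  if (task == "regression") {
    adult <- setdiff(unique(df$oil), "avocado")
    if (length(adult) != 1L)
      stop("a regression dataset must contain exactly one adulterant oil",
           call. = FALSE)
  }
  structure(df, task = task, provenance = provenance,
            class = c("oil_dataset", "data.frame"))
}

#' @export
print.oil_dataset <- function(x, ...) {
  cat(sprintf("<oil_dataset> %d samples, task=%s, illuminant=%s\n",
              nrow(x), attr(x, "task"), x$illuminant[1L]))
  tab <- table(x$oil)
  cat("  oils:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Feature matrix of a dataset
#'
#' @param ds An [oil_dataset()].
#' @return Numeric matrix with columns r, g, b and sample_id rownames.
#' @export
features_matrix <- function(ds) {
  stopifnot(inherits(ds, "oil_dataset"))
  m <- as.matrix(ds[, c("r", "g", "b")])
  rownames(m) <- ds$sample_id
  m
}

#' Read / write the dataset interchange CSV
#'
#' One row per sample with header
#' `sample_id, oil, fraction, replicate, illuminant, R, G, B, C, r, g, b`.
#' Numeric fields are written with 17 significant digits so that the
#' write/read round trip is lossless at double precision.
#'
#' @param path File path.
#' @param task,provenance Passed to [oil_dataset()] on read; `task` defaults
#'   to the value stored in the file's provenance comment, else
#'   "classification".
#' @return `read_dataset()` returns an [oil_dataset()]; `write_dataset()`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path, task = NULL) {
  header <- readLines(path, n = 2L)
  stored_task <- NULL
  if (length(header) >= 1L && startsWith(header[1L], "#")) {
    m <- regmatches(header[1L], regexec("task=(\\w+)", header[1L]))[[1L]]
    if (length(m) == 2L) stored_task <- m[2L]
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(dataset_columns(), names(df))
  if (length(missing_cols) > 0L)
    stop("file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  oil_dataset(df, task = task %||% stored_task %||% "classification",
              provenance = list(source = path))
}

#' @rdname read_dataset
#' @param ds An [oil_dataset()] to write.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "oil_dataset"))
  out <- as.data.frame(ds)
  for (col in c("fraction", "R", "G", "B", "C", "r", "g", "b"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  seed <- attr(ds, "provenance")$seed
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# blendsense dataset task=%s seed=%s\n", attr(ds, "task"),
              if (is.null(seed)) "NA" else seed), file = con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
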