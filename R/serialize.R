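# Plain-text (JSON) model persistence; lossless at double precision.

serialize_schema_version <- "1.0"

#' Write a fitted model to JSON
#'
#' Serializes `lda_model`, `mlr_model` and `lssvm_model` objects to a JSON
#' document carrying the model type, a schema version and every numeric
#' field at full double precision, so the write/read round trip is lossless.
#'
#' @param model A fitted model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  type <- intersect(class(model), c("lda_model", "mlr_model", "lssvm_model"))
  if (length(type) != 1L)
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  payload <- unclass(model)
  doc <- list(schema = "blendsense-model", version = serialize_schema_version,
              type = type, fields = payload)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path File written by [write_model()].
#' @return The model with its original class.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "blendsense-model"))
    stop("not a blendsense model file", call. = FALSE)
  fields <- doc$fields
  if (doc$type == "lssvm_model") {
    fields$X <- as.matrix(fields$X)
    fields$alpha <- as.matrix(fields$alpha)
    if (length(fields$labels) == 0L) {
      fields$labels <- NULL
      fields$alpha <- fields$alpha[, 1L]
      dim(fields$alpha) <- c(length(fields$alpha), 1L)
    } else {
      colnames(fields$alpha) <- fields$labels
      names(fields$bias) <- fields$labels
    }
  }
  if (doc$type == "lda_model") {
    fields$means <- as.matrix(fields$means)
    rownames(fields$means) <- fields$labels
    fields$cov <- as.matrix(fields$cov)
  }
  structure(fields, class = doc$type)
}
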