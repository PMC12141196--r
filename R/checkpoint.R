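# JSON checkpoint serialization. jsonlite::serializeJSON preserves R types,
# attributes and classes exactly (matrices, integer vs double, S3 classes),
# so checkpoints are plain text yet reload bit-identically.

#' Save a model (or phase-1 result) checkpoint as JSON
#'
#' The checkpoint bundles every parameter matrix, the group partitions, the
#' graph, the configuration and (if supplied) the standardization statistics,
#' so that training-time groupings and scaling are reproduced exactly at
#' inference.
#'
#' @param object A `fuseomics_model` or the list returned by
#'   [train_phase1()].
#' @param path Output file path (`.json`).
#' @param standardization Optional stats list from
#'   [standardize_multiomics()].
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path, standardization = NULL) {
  payload <- list(
    format = "fuseomics-checkpoint-1",
    kind = if (inherits(object, "fuseomics_model")) "model" else "phase1",
    object = object,
    standardization = standardization
  )
  # I(17) = 17 *significant* digits: doubles round-trip bit-exactly
  writeLines(jsonlite::serializeJSON(payload, digits = I(17)), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Path to the JSON checkpoint.
#' @return List with `object` (model or phase-1 result), `kind` and
#'   `standardization` (stats list or NULL).
#' @export
load_checkpoint <- function(path) {
  payload <- tryCatch(
    jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                    collapse = "\n")),
    error = function(e) abort_("cannot read checkpoint '", path, "': ",
                               conditionMessage(e))
  )
  if (!identical(payload$format, "fuseomics-checkpoint-1")) {
    abort_("'", path, "' is not a fuseomics checkpoint")
  }
  payload[c("object", "kind", "standardization")]
}
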