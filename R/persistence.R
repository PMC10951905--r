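#' Save a fitted pipeline to a self-contained archive
#'
#' The archive (an RDS container with a versioned layout) holds everything
#' standardisation needs: the pipeline setting, CP definitions with
#' reference values, category codebooks, the bin partition, per-bin targets
#' and the fitted regressors (linear models as plain coefficient vectors;
#' SVR and tree ensembles as their native fitted objects, with the library
#' versions recorded). Archives do not depend on the training data files;
#' with `include_fingerprint = TRUE` a record/pixel count and data hash are
#' kept for training traceability, without it the archive standardises
#' identically but cannot be traced back.
#'
#' @param model A fitted `cpie_model`.
#' @param path Output file path (conventionally `.t1pipe`).
#' @param include_fingerprint Keep the training fingerprint?
#' @return `path`, invisibly.
#' @export
save_pipeline <- function(model, path, include_fingerprint = TRUE) {
  if (!inherits(model, "cpie_model")) abort_input("save_pipeline needs a fitted cpie_model")
  payload <- unclass(model)
  if (!include_fingerprint) payload$training_fingerprint <- NULL
  archive <- list(format = "t1stand-pipeline", format_version = 1L,
                  created = format(Sys.time(), tz = "UTC"), payload = payload)
  ok <- try(saveRDS(archive, path), silent = TRUE)
  if (inherits(ok, "try-error")) abort_io(paste0("cannot write pipeline archive: ", path))
  invisible(path)
}

#' Load a pipeline archive
#'
#' @param path Archive written by [save_pipeline()].
#' @return A functional `cpie_model`.
#' @export
load_pipeline <- function(path) {
  archive <- tryCatch(readRDS(path), error = function(e) {
    abort_io(paste0("cannot read pipeline archive '", path, "': ", conditionMessage(e)))
  })
  if (!is.list(archive) || !identical(archive$format, "t1stand-pipeline")) {
    abort_io(paste0("'", path, "' is not a pipeline archive"))
  }
  if (!identical(archive$format_version, 1L)) {
    abort_io(paste0("unsupported pipeline archive format_version: ",
                    archive$format_version %||% "<missing>", " (supported: 1)"))
  }
  structure(archive$payload, class = "cpie_model")
}
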