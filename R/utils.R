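# shared internal helpers

abort_input <- function(msg, ...) rlang::abort(msg, class = "t1stand_input_error", ...)
abort_config <- function(msg, ...) rlang::abort(msg, class = "t1stand_config_error", ...)
abort_extraction <- function(msg, ...) rlang::abort(msg, class = "t1stand_extraction_error", ...)
abort_application <- function(msg, ...) rlang::abort(msg, class = "t1stand_application_error", ...)
abort_computation <- function(msg, ...) rlang::abort(msg, class = "t1stand_computation_error", ...)
abort_io <- function(msg, ...) rlang::abort(msg, class = "t1stand_io_error", ...)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang .data
NULL

# md5 of an arbitrary R object, via a temporary file (tools::md5sum is file-based)
object_md5 <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f), add = TRUE)
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# draw a sub-seed deterministically from a master seed, staying inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
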