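# Classed error conditions shared across the package.
#
# Every domain error is signalled as a condition with classes
# c("vc_<Name>", "vc_error", "error", "condition") so callers (and the CLI)
# can dispatch on the machine-readable name rather than the message text.

vc_abort <- function(name, message, ...) {
  cond <- structure(
    class = c(paste0("vc_", name), "vc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), error_name = name, ...)
  )
  stop(cond)
}

#' Extract the machine-readable name of a vcurate error
#'
#' @param cond A condition object raised by the package.
#' @return The error name (e.g. `"DuplicateRecord"`), or `NA` for foreign
#'   conditions.
#' @export
vc_error_name <- function(cond) {
  if (!is.null(cond$error_name)) cond$error_name else NA_character_
}

`%||%` <- function(a, b) if (is.null(a)) b else a
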