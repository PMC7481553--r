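# Structured conditions and logging shared by all modules.
#
# Every error raised by the package carries class c("lfa_<kind>", "lfa_error",
# "error", "condition") so callers can branch on the failure kind rather than
# parse messages.

lfa_stop <- function(kind, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ..., class = c(kind, "lfa_error"),
                      call = call))
}

lfa_io_error         <- function(msg, ...) lfa_stop("lfa_io_error", msg, ...)
lfa_format_error     <- function(msg, ...) lfa_stop("lfa_format_error", msg, ...)
lfa_usage_error      <- function(msg, ...) lfa_stop("lfa_usage_error", msg, ...)
lfa_geometry_error   <- function(msg, ...) lfa_stop("lfa_geometry_error", msg, ...)
lfa_degenerate_input <- function(msg, ...) lfa_stop("lfa_degenerate_input", msg, ...)
lfa_detection_error  <- function(msg, ...) lfa_stop("lfa_detection_error", msg, ...)
lfa_schema_error     <- function(msg, ...) lfa_stop("lfa_schema_error", msg, ...)
lfa_parse_error      <- function(msg, ...) lfa_stop("lfa_parse_error", msg, ...)
lfa_integrity_error  <- function(msg, ...) lfa_stop("lfa_integrity_error", msg, ...)
lfa_insufficient_data <- function(msg, ...) lfa_stop("lfa_insufficient_data", msg, ...)
lfa_degenerate_fit   <- function(msg, ...) lfa_stop("lfa_degenerate_fit", msg, ...)
lfa_range_error      <- function(msg, ...) lfa_stop("lfa_range_error", msg, ...)

.log_levels <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

#' Set the package log level
#'
#' Log messages at or above this level are written to standard error.
#'
#' @param level One of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
lfa_log_level <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- getOption("lfaquant.log_level", "info")
  options(lfaquant.log_level = level)
  invisible(old)
}

lfa_log <- function(level, ...) {
  threshold <- .log_levels[[getOption("lfaquant.log_level", "info")]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[lfaquant %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

lfa_warn <- function(msg, kind = "lfa_warning") {
  warning(warningCondition(msg, class = c(kind, "lfa_warning")))
  invisible(NULL)
}
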