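# Structured error conditions.  Every error thrown by the package carries the
# class "blastvista_error" plus one of the subclasses below, so callers can
# dispatch with tryCatch() without matching message text.

bv_abort <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "blastvista_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' @noRd
abort_unrecognised_format <- function(message, ...) {
  bv_abort("unrecognised_format", message, ...)
}

#' @noRd
abort_malformed_input <- function(message, issue = NULL, ...) {
  bv_abort("malformed_input", message, issue = issue, ...)
}

#' @noRd
abort_inconsistent_hsp <- function(message, ...) {
  bv_abort("inconsistent_hsp", message, ...)
}

#' @noRd
abort_invalid_spec <- function(message, ...) {
  bv_abort("invalid_spec", message, ...)
}

abort_usage <- function(message, ...) {
  bv_abort("usage_error", message, ...)
}

#' Create a parse issue record
#'
#' Issues are collected while parsing: warnings are always collected, errors
#' are raised in strict mode and collected (with the offending unit dropped)
#' in lenient mode.
#'
#' @param severity `"warning"` or `"error"`.
#' @param message Human-readable description.
#' @param line_no 1-based line number in the input, or `NA`.
#' @return A list of class `parse_issue`.
#' @export
parse_issue <- function(severity = c("warning", "error"), message, line_no = NA_integer_) {
  severity <- match.arg(severity)
  structure(
    list(severity = severity, line_no = as.integer(line_no), message = message),
    class = "parse_issue"
  )
}

#' @export
format.parse_issue <- function(x, ...) {
  loc <- if (is.na(x$line_no)) "" else sprintf(" (line %d)", x$line_no)
  sprintf("[%s]%s %s", x$severity, loc, x$message)
}

#' @export
print.parse_issue <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Mutable issue collector used by the parsers.
new_issue_collector <- function(mode) {
  env <- new.env(parent = emptyenv())
  env$issues <- list()
  env$mode <- mode
  env
}

# Record an issue; in strict mode an error-severity issue aborts parsing.
collect_issue <- function(collector, severity, message, line_no = NA_integer_) {
  issue <- parse_issue(severity, message, line_no)
  if (severity == "error" && collector$mode == "strict") {
    abort_malformed_input(format(issue), issue = issue)
  }
  collector$issues[[length(collector$issues) + 1L]] <- issue
  invisible(issue)
}
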