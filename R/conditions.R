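# Error conditions used across the package. Data errors (bad input files,
# inconsistent tables) are distinguished from usage errors (bad arguments)
# so the command-line dispatcher can map them to exit codes 1 and 2.

cs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cs_error"), call = call))
}

#' @noRd
cs_parse_error <- function(msg) cs_stop(msg, c("cs_parse_error", "cs_data_error"))

#' @noRd
cs_structural_error <- function(msg) cs_stop(msg, c("cs_structural_error", "cs_data_error"))

#' @noRd
cs_data_error <- function(msg) cs_stop(msg, "cs_data_error")

#' @noRd
cs_usage_error <- function(msg) cs_stop(msg, "cs_usage_error")

# Verbosity-gated logging to stderr; level 0 silences everything.
cs_log <- function(..., verbose = getOption("chimeraScreen.verbose", 1L), level = 1L) {
  if (verbose >= level) message(...)
  invisible(NULL)
}
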