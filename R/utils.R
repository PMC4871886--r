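#' @keywords internal
"_PACKAGE"

# INFO-level logging; suppressible via options(micrograze.verbose = FALSE)
mg_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("micrograze.verbose", TRUE))) {
    message(sprintf("INFO [%s] %s", stage, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

mg_warn <- function(stage, fmt, ...) {
  warning(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed float formatting used by all writers: 6 significant digits
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
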