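# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation errors -> 2, I/O errors -> 3.

stopValidation <- function(msg, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c("dyadiar_validation_error", "dyadiar_error")))
}

stopIO <- function(msg, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c("dyadiar_io_error", "dyadiar_error")))
}

assertThat <- function(ok, msg) {
  if (!isTRUE(ok)) stopValidation(msg)
  invisible(TRUE)
}

# new() runs validity checks that raise plain errors; user-facing
# constructors funnel them through here so callers get classed conditions
newValidated <- function(Class, ...) {
  tryCatch(
    new(Class, ...),
    error = function(e) stopValidation(conditionMessage(e))
  )
}
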