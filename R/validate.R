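# Classed error helpers so callers can distinguish bad inputs from bad files.

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("ohci_validation_error", "error", "condition")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("ohci_format_error", "error", "condition")))
}

stop_generation <- function(msg) {
  stop(errorCondition(msg, class = c("ohci_generation_error", "error", "condition")))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_validation(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_validation(sprintf("`%s` must be a single number in [0, 1]", name))
  invisible(x)
}
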