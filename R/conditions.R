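# Classed conditions so callers (and the CLI) can distinguish failure modes.

stop_stackops <- function(subclass, message, call = sys.call(-1), ...) {
  cnd <- structure(
    class = c(subclass, "stackops_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

stop_validation <- function(message, report = NULL)
  stop_stackops("stackops_validation_error", message, report = report)

stop_parameter <- function(message)
  stop_stackops("stackops_parameter_error", message)

stop_storage <- function(message)
  stop_stackops("stackops_storage_error", message)

stop_not_found <- function(message)
  stop_stackops("stackops_not_found_error", message)

stop_format <- function(message)
  stop_stackops("stackops_format_error", message)

stop_detection <- function(message)
  stop_stackops("stackops_detection_error", message)

stop_execution <- function(message)
  stop_stackops("stackops_execution_error", message)

# Half-up rounding used wherever intensities are re-quantized.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
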