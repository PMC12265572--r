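# Structured error conditions so callers can distinguish degenerate data
# (histogram with a single class, empty foreground) from plain misuse.

stop_condition <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "spotlight3d_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_degenerate_histogram <- function(message) {
  stop_condition("degenerate_histogram_error", message)
}

stop_empty_foreground <- function(message) {
  stop_condition("empty_foreground_error", message)
}

stop_validation <- function(message) {
  stop_condition("validation_error", message)
}

stop_undefined_distance <- function(message) {
  stop_condition("undefined_distance_error", message)
}
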