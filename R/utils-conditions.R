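# Classed conditions so callers (and the command-line front end) can map
# failures to exit codes: config -> 2, data/format -> 3, empty result -> 4.

stopCondition <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "faersignalError", "error", "condition"),
    list(message = message, call = call)
  ))
}

stopConfig <- function(message) stopCondition("faersignalConfigError", message)
stopFormat <- function(message) stopCondition("faersignalFormatError", message)
stopEmpty  <- function(message) stopCondition("faersignalEmptyError", message)

`%||%` <- function(x, y) if (is.null(x)) y else x
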