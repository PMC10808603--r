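# Classed conditions so callers can distinguish failure modes programmatically.
# Every user-facing error in the package goes through hs_error() with one of
# the hs_* classes below; tests assert on the class, not the message.

hs_error <- function(class, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "heartseg_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

hs_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "heartseg_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
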