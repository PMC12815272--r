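# Classed conditions used across the package. Every error inherits from
# "ww_error" so callers can catch pipeline failures in one clause.

ww_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ww_error", "error"), call = call))
}

ww_warn <- function(msg, class = "ww_warning") {
  warning(warningCondition(msg, class = c(class, "warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
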