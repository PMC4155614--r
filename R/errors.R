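# Structured conditions so the CLI can map failure modes to exit codes.

sdd_error <- function(message, class, ...) {
  stop(structure(
    class = c(class, "sdd_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
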