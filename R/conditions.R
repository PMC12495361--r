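# Classed conditions used across the package. Every error raised by
# breathtrace carries class c("bt_<kind>", "bt_error", ...) so callers
# (and the command-line wrapper) can map failures to exit codes without
# string-matching messages.

bt_abort <- function(kind, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("bt_", kind), "bt_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @keywords internal
bt_stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    bt_abort("validation_error", sprintf("%s must be finite", what))
  }
  invisible(x)
}
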