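#' Construct a breathing trace
#'
#' A breathing trace is the package's central container: an ordered series of
#' `(t, amplitude, xray_on)` samples, where `t` is in seconds, `amplitude` is
#' the anterior-posterior displacement in mm and `xray_on` flags beam-on
#' samples.
#'
#' @param t Numeric vector of timestamps (s), strictly increasing.
#' @param amplitude Numeric vector of AP amplitudes (mm).
#' @param xray_on Logical vector of beam-on flags (recycled if length 1).
#' @param label Free-text label (system or scenario name).
#' @param sample_rate_hz Nominal sampling rate; inferred from the median
#'   timestamp spacing when `NULL`.
#' @return An object of class `breathing_trace`.
#' @export
breathing_trace <- function(t, amplitude, xray_on = FALSE, label = "",
                            sample_rate_hz = NULL) {
  t <- as.numeric(t); amplitude <- as.numeric(amplitude)
  if (length(t) != length(amplitude)) {
    bt_abort("validation_error", "t and amplitude must have equal length")
  }
  if (length(xray_on) == 1L) xray_on <- rep(as.logical(xray_on), length(t))
  xray_on <- as.logical(xray_on)
  if (length(xray_on) != length(t)) {
    bt_abort("validation_error", "xray_on must match the number of samples")
  }
  if (length(t) > 0L) {
    bt_stopifnot_finite(t, "t")
    bt_stopifnot_finite(amplitude, "amplitude")
    if (any(is.na(xray_on))) {
      bt_abort("validation_error", "xray_on must be TRUE/FALSE")
    }
    if (any(diff(t) <= 0)) {
      bt_abort("validation_error", "timestamps must be strictly increasing")
    }
  }
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- if (length(t) >= 2L) 1 / stats::median(diff(t)) else NA_real_
  }
  structure(
    list(samples = data.frame(t = t, amplitude = amplitude, xray_on = xray_on),
         label = label, sample_rate_hz = sample_rate_hz),
    class = "breathing_trace"
  )
}

#' @export
print.breathing_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<breathing_trace> %s: %d samples", x$label, n))
  if (n > 0L) {
    cat(sprintf(", t = [%.3f, %.3f] s, amplitude range [%.2f, %.2f] mm, %d beam-on",
                x$samples$t[1], x$samples$t[n],
                min(x$samples$amplitude), max(x$samples$amplitude),
                sum(x$samples$xray_on)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.breathing_trace <- function(x) nrow(x$samples)

# Median sampling interval of a trace, in seconds.
trace_dt <- function(trace) {
  t <- trace$samples$t
  if (length(t) < 2L) bt_abort("validation_error", "trace too short")
  stats::median(diff(t))
}

# Centered moving-average smoother with window given in seconds; the window
# is rounded to an odd number of samples and shrunk at the edges. window = 0
# returns the input untouched.
smooth_trace_values <- function(t, x, window_s) {
  n <- length(x)
  if (window_s <= 0 || n < 3L) return(x)
  dt <- stats::median(diff(t))
  half <- max(0L, floor(window_s / dt / 2))
  if (half == 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
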