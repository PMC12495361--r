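# Patient-facing guidance logic: the cos^6 target waveform, static (DIBH)
# and dynamic (4DCT) breathing windows, and the green/yellow/red state
# classification. This is the headless core of the bedside display; the
# actual rendering (ball + shaded window) is a thin presentation layer on
# top of the per-sample states produced here.

#' Guidance waveform parameters
#'
#' @param A Peak-to-trough amplitude in mm (study default 30).
#' @param T Cycle duration in s (study default 10).
#' @param exponent Even cosine exponent >= 2 (default 6); higher exponents
#'   lengthen the end-exhale dwell relative to inhale, mimicking natural
#'   breathing.
#' @return A list of class `guidance_params`.
#' @export
guidance_params <- function(A = 30, T = 10, exponent = 6) {
  if (!is.finite(A) || A <= 0) bt_abort("config_error", "A must be > 0")
  if (!is.finite(T) || T <= 0) bt_abort("config_error", "T must be > 0")
  if (exponent < 2 || exponent %% 2 != 0) {
    bt_abort("config_error", "exponent must be an even integer >= 2")
  }
  structure(list(A = A, T = T, exponent = exponent),
            class = "guidance_params")
}

#' Cosine-power guidance waveform
#'
#' `g(t) = A * (1 - cos^k(pi * t / T))` with even exponent `k`: `g(0) = 0`
#' (end-exhale resting baseline), `g(T/2) = A` (end-inhale), period `T`,
#' range exactly `[0, A]`.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param params A [guidance_params()].
#' @return Target amplitude(s) in mm.
#' @export
guidance_waveform <- function(t, params = guidance_params()) {
  params$A * (1 - cos(pi * t / params$T)^params$exponent)
}

#' Construct a breathing window
#'
#' @param lower,upper Window bounds in mm (`lower < upper`).
#' @param mode `"static_dibh"` or `"dynamic_4dct"`.
#' @param edge_margin Width of the "at the edge" (yellow) zone inside each
#'   bound, mm; defaults to 10% of the window width and must stay below half
#'   the width.
#' @return A list of class `breathing_window`.
#' @export
breathing_window <- function(lower, upper, mode = c("static_dibh", "dynamic_4dct"),
                             edge_margin = 0.1 * (upper - lower)) {
  mode <- match.arg(mode)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    bt_abort("config_error", "need finite lower < upper")
  }
  if (edge_margin < 0 || edge_margin >= (upper - lower) / 2) {
    bt_abort("config_error", "edge_margin must be in [0, width/2)")
  }
  structure(list(lower = lower, upper = upper, mode = mode,
                 edge_margin = edge_margin), class = "breathing_window")
}

#' Dynamic 4DCT breathing window at time t
#'
#' A window of constant width `2 * half_width` centred on the guidance
#' waveform. Bounds may be negative near end-exhale; clipping is left to the
#' display layer.
#'
#' @param t Time in seconds.
#' @param params A [guidance_params()].
#' @param half_width Half-width of the window, mm.
#' @param edge_margin_frac Yellow-zone width as a fraction of window width.
#' @return A [breathing_window()] with mode `"dynamic_4dct"`.
#' @export
dynamic_window <- function(t, params = guidance_params(), half_width = 2.5,
                           edge_margin_frac = 0.1) {
  if (!is.finite(half_width) || half_width <= 0) {
    bt_abort("config_error", "half_width must be > 0")
  }
  g <- guidance_waveform(t, params)
  breathing_window(g - half_width, g + half_width, mode = "dynamic_4dct",
                   edge_margin = edge_margin_frac * 2 * half_width)
}

#' Classify an amplitude against a breathing window
#'
#' `"outside"` (red) when the amplitude lies beyond the bounds, `"edge"`
#' (yellow) when inside but within `edge_margin` of a bound, `"within"`
#' (green) otherwise. Vectorised over `amplitude`.
#'
#' @param amplitude Amplitude(s) in mm.
#' @param window A [breathing_window()].
#' @return Character vector of states.
#' @export
classify_state <- function(amplitude, window) {
  stopifnot(inherits(window, "breathing_window"))
  out <- ifelse(amplitude < window$lower | amplitude > window$upper, "outside",
                ifelse(amplitude - window$lower < window$edge_margin |
                         window$upper - amplitude < window$edge_margin,
                       "edge", "within"))
  out
}

#' Replay a breathing trace through the feedback display logic
#'
#' Classifies every sample of the trace against either a fixed static window
#' or the dynamic window following the guidance waveform, and summarises the
#' fraction of time spent in each state.
#'
#' @param trace A [breathing_trace()].
#' @param window A static [breathing_window()], or `NULL` for dynamic mode.
#' @param params A [guidance_params()] (dynamic mode).
#' @param half_width Dynamic window half-width, mm.
#' @param edge_margin_frac Yellow-zone fraction of window width.
#' @return A list of class `feedback_session`: `states` (data frame with
#'   `t`, `amplitude`, `lower`, `upper`, `state`) and `occupancy` (named
#'   fractions `within`, `edge`, `outside`).
#' @export
run_session <- function(trace, window = NULL, params = guidance_params(),
                        half_width = 2.5, edge_margin_frac = 0.1) {
  s <- trace$samples
  if (nrow(s) == 0L) bt_abort("validation_error", "empty trace")
  if (!is.null(window)) {
    stopifnot(inherits(window, "breathing_window"))
    lower <- rep(window$lower, nrow(s))
    upper <- rep(window$upper, nrow(s))
    margin <- window$edge_margin
  } else {
    g <- guidance_waveform(s$t, params)
    lower <- g - half_width
    upper <- g + half_width
    margin <- edge_margin_frac * 2 * half_width
  }
  a <- s$amplitude
  state <- ifelse(a < lower | a > upper, "outside",
                  ifelse(a - lower < margin | upper - a < margin,
                         "edge", "within"))
  occ <- vapply(c(within = "within", edge = "edge", outside = "outside"),
                function(k) mean(state == k), numeric(1))
  structure(list(
    states = data.frame(t = s$t, amplitude = a, lower = lower, upper = upper,
                        state = state),
    occupancy = occ
  ), class = "feedback_session")
}

#' @export
print.feedback_session <- function(x, ...) {
  cat(sprintf("<feedback_session> %d samples | within %.1f%% | edge %.1f%% | outside %.1f%%\n",
              nrow(x$states), 100 * x$occupancy[["within"]],
              100 * x$occupancy[["edge"]], 100 * x$occupancy[["outside"]]))
  invisible(x)
}
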