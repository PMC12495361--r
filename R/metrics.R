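# DIBH and 4DCT signal-quality metrics.
#
# DIBH: reproducibility = spread of mean amplitudes across successive
# breath-hold plateaus; stability = intra-breath-hold drift (OLS slope).
# 4DCT: per-cycle peak-to-trough amplitude and max-to-max cycle duration;
# baseline shift = amplitude(last end-expiration minimum) minus
# amplitude(first end-expiration minimum), negative meaning a sagging
# baseline. All SDs use the sample (n - 1) convention.

#' Detect breath-hold plateaus in a breathing trace
#'
#' A plateau is a maximal run of samples whose smoothed derivative magnitude
#' stays within `slope_tol` and whose level exceeds an adaptive height
#' threshold (`height_frac` of the trace's 95th-percentile amplitude),
#' lasting at least `min_duration`. The coarse run found on the smoothed
#' signal is then refined outward using raw first differences, so on clean
#' signals the reported duration lands on the flat-top corners to within one
#' sample. Mean amplitude and drift are computed over the plateau interior
#' after trimming `trim_frac` of the samples at each end, which keeps
#' inhale/exhale ramps from biasing the drift estimate.
#'
#' @param trace A [breathing_trace()].
#' @param min_duration Minimum plateau duration in s (default 5, the
#'   breath-hold length volunteers are coached to sustain).
#' @param slope_tol Maximum smoothed-derivative magnitude, mm/s.
#' @param trim_frac Fraction of samples trimmed at each end of a plateau
#'   before computing mean amplitude and drift.
#' @param smooth_window Moving-average window (s) used for the coarse mask.
#' @param height_frac Fraction of the 95th-percentile amplitude a plateau
#'   must exceed.
#' @return Data frame with one row per plateau: `t_start`, `t_end`,
#'   `duration`, `mean_amplitude`, `drift`, `n_samples`. Zero rows when no
#'   segment qualifies.
#' @export
detect_plateaus <- function(trace, min_duration = 5, slope_tol = 1.0,
                            trim_frac = 0.1, smooth_window = 0.25,
                            height_frac = 0.5) {
  s <- trace$samples
  if (nrow(s) < 3L) bt_abort("validation_error", "trace too short")
  t <- s$t; x <- s$amplitude
  dt <- trace_dt(trace)
  if (t[length(t)] - t[1] < min_duration) {
    bt_abort("validation_error", "trace shorter than min_duration")
  }
  xs <- smooth_trace_values(t, x, smooth_window)
  # derivative by central differences spanning the smoothing window: a
  # one-sample difference would amplify residual noise ~20x at typical rates
  n_all <- length(xs)
  h <- max(1L, floor(smooth_window / dt / 2))
  ilo <- pmax(1L, seq_len(n_all) - h)
  ihi <- pmin(n_all, seq_len(n_all) + h)
  deriv <- (xs[ihi] - xs[ilo]) / (t[ihi] - t[ilo])
  height_thr <- height_frac * stats::quantile(xs, 0.95, names = FALSE)
  mask <- abs(deriv) <= slope_tol & xs >= height_thr
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)

  out <- list()
  for (k in runs) {
    i0 <- starts[k]; i1 <- ends[k]
    # refine edges with raw first differences (exact on noise-free corners;
    # a no-op under realistic noise, where raw diffs exceed slope_tol)
    while (i0 > 1L &&
           abs(x[i0] - x[i0 - 1L]) <= slope_tol * (t[i0] - t[i0 - 1L]) &&
           x[i0 - 1L] >= height_thr) i0 <- i0 - 1L
    n <- length(x)
    while (i1 < n &&
           abs(x[i1 + 1L] - x[i1]) <= slope_tol * (t[i1 + 1L] - t[i1]) &&
           x[i1 + 1L] >= height_thr) i1 <- i1 + 1L
    if (t[i1] - t[i0] < min_duration) next
    len <- i1 - i0 + 1L
    trim <- floor(trim_frac * len)
    j0 <- i0 + trim; j1 <- i1 - trim
    if (j1 - j0 + 1L < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      t_start = t[i0], t_end = t[i1], duration = t[i1] - t[i0],
      mean_amplitude = mean(x[j0:j1]),
      drift = plateau_drift(t[j0:j1], x[j0:j1]),
      n_samples = len
    )
  }
  if (length(out) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), mean_amplitude = numeric(0),
                      drift = numeric(0), n_samples = integer(0)))
  }
  do.call(rbind, out)
}

#' Intra-breath-hold drift of a plateau segment
#'
#' Ordinary least-squares slope of amplitude versus time, mm/s.
#'
#' @param t Timestamps (s), length >= 2.
#' @param amplitude Amplitudes (mm).
#' @return Slope in mm/s.
#' @export
plateau_drift <- function(t, amplitude) {
  if (length(t) < 2L || length(t) != length(amplitude)) {
    bt_abort("validation_error", "need >= 2 paired samples")
  }
  if (max(t) - min(t) <= 0) {
    bt_abort("degenerate_fit", "all timestamps equal; slope undefined")
  }
  unname(stats::lm.fit(cbind(1, t), amplitude)$coefficients[2])
}

#' Baseline shift of a breathing trace
#'
#' The difference between the amplitude at the last end-expiration minimum
#' and at the first end-expiration minimum; negative values indicate a
#' sagging baseline. Minima are local minima of the lightly smoothed trace
#' passing the same prominence rule as cycle maxima; amplitudes are read
#' from the smoothed trace, which suppresses single-sample tracking noise
#' without biasing the difference (the smoothing attenuation is identical at
#' both minima of a quasi-periodic signal).
#'
#' @param trace A [breathing_trace()].
#' @param prominence_frac Minimum prominence as a fraction of signal range.
#' @param min_separation Minimum spacing between minima, s.
#' @param smooth_window Moving-average window, s (0 disables smoothing).
#' @return Baseline shift in mm.
#' @export
baseline_shift <- function(trace, prominence_frac = 0.2,
                           min_separation = 0.5, smooth_window = 0.25) {
  s <- trace$samples
  if (nrow(s) < 3L) bt_abort("undefined_metric", "trace too short for minima")
  xs <- smooth_trace_values(s$t, s$amplitude, smooth_window)
  dt <- trace_dt(trace)
  mins <- find_minima(xs, prom_min = prominence_frac * (max(xs) - min(xs)),
                      min_dist = max(1L, ceiling(min_separation / dt)))
  if (length(mins) < 2L) {
    bt_abort("undefined_metric",
             "fewer than two end-expiration minima detected")
  }
  xs[mins[length(mins)]] - xs[mins[1]]
}

#' Segment a trace into breathing cycles (max-to-max)
#'
#' Local maxima with prominence at least `prominence_frac` of the signal
#' range and pairwise separation at least `min_separation` define cycle
#' boundaries; each cycle's amplitude is the peak-to-trough range within the
#' inter-peak interval and its duration the inter-peak spacing.
#'
#' @inheritParams baseline_shift
#' @return Data frame with one row per cycle: `t_peak_start`, `t_peak_end`,
#'   `duration`, `amplitude`. Zero rows when fewer than two maxima qualify.
#' @export
segment_cycles <- function(trace, prominence_frac = 0.2,
                           min_separation = 0.5) {
  s <- trace$samples
  if (nrow(s) < 3L) {
    return(data.frame(t_peak_start = numeric(0), t_peak_end = numeric(0),
                      duration = numeric(0), amplitude = numeric(0)))
  }
  x <- s$amplitude; t <- s$t
  dt <- trace_dt(trace)
  pk <- find_peaks(x, prom_min = prominence_frac * (max(x) - min(x)),
                   min_dist = max(1L, ceiling(min_separation / dt)))
  if (length(pk) < 2L) {
    return(data.frame(t_peak_start = numeric(0), t_peak_end = numeric(0),
                      duration = numeric(0), amplitude = numeric(0)))
  }
  a <- pk[-length(pk)]; b <- pk[-1]
  data.frame(
    t_peak_start = t[a], t_peak_end = t[b], duration = t[b] - t[a],
    amplitude = vapply(seq_along(a), function(i) {
      seg <- x[a[i]:b[i]]; max(seg) - min(seg)
    }, numeric(1))
  )
}

#' DIBH quality report
#'
#' Detects breath-hold plateaus and summarises reproducibility (mean and
#' sample SD of per-plateau mean amplitudes) and stability (mean and sample
#' SD of per-plateau drifts). With a single plateau the SDs are reported as
#' `NA` and flagged undefined.
#'
#' @param trace A [breathing_trace()].
#' @param ... Passed on to [detect_plateaus()].
#' @return A list of class `dibh_report`: `plateaus`, `amplitude_mean`,
#'   `amplitude_sd`, `drift_mean`, `drift_sd`, `sd_defined`.
#' @export
dibh_report <- function(trace, ...) {
  pl <- detect_plateaus(trace, ...)
  if (nrow(pl) == 0L) {
    bt_abort("undefined_metric", "no breath-hold plateau detected")
  }
  sd_defined <- nrow(pl) >= 2L
  structure(list(
    plateaus = pl,
    amplitude_mean = mean(pl$mean_amplitude),
    amplitude_sd = if (sd_defined) stats::sd(pl$mean_amplitude) else NA_real_,
    drift_mean = mean(pl$drift),
    drift_sd = if (sd_defined) stats::sd(pl$drift) else NA_real_,
    sd_defined = sd_defined
  ), class = "dibh_report")
}

#' @export
print.dibh_report <- function(x, ...) {
  cat(sprintf("<dibh_report> %d plateaus | amplitude %.1f +/- %s mm | drift %.1f +/- %s mm/s\n",
              nrow(x$plateaus), x$amplitude_mean,
              if (x$sd_defined) sprintf("%.1f", x$amplitude_sd) else "NA",
              x$drift_mean,
              if (x$sd_defined) sprintf("%.1f", x$drift_sd) else "NA"))
  invisible(x)
}

#' 4DCT quality report
#'
#' Segments breathing cycles and summarises per-cycle amplitude and duration
#' (mean, sample SD) together with the trace's baseline shift.
#'
#' @param trace A [breathing_trace()].
#' @param prominence_frac,min_separation Passed to [segment_cycles()] and
#'   [baseline_shift()].
#' @param smooth_window Passed to [baseline_shift()].
#' @return A list of class `fourd_report`: `cycles`, `amplitude_mean`,
#'   `amplitude_sd`, `duration_mean`, `duration_sd`, `baseline_shift`.
#' @export
fourd_report <- function(trace, prominence_frac = 0.2, min_separation = 0.5,
                         smooth_window = 0.25) {
  cy <- segment_cycles(trace, prominence_frac, min_separation)
  if (nrow(cy) < 2L) {
    bt_abort("undefined_metric", "fewer than two breathing cycles detected")
  }
  structure(list(
    cycles = cy,
    amplitude_mean = mean(cy$amplitude),
    amplitude_sd = stats::sd(cy$amplitude),
    duration_mean = mean(cy$duration),
    duration_sd = stats::sd(cy$duration),
    baseline_shift = baseline_shift(trace, prominence_frac, min_separation,
                                    smooth_window)
  ), class = "fourd_report")
}

#' @export
print.fourd_report <- function(x, ...) {
  cat(sprintf("<fourd_report> %d cycles | amplitude %.1f +/- %.1f mm | duration %.1f +/- %.1f s | baseline shift %.2f mm\n",
              nrow(x$cycles), x$amplitude_mean, x$amplitude_sd,
              x$duration_mean, x$duration_sd, x$baseline_shift))
  invisible(x)
}

#' Cohort aggregation of per-subject (mean, SD) pairs
#'
#' Reproduces the two aggregation rows of a per-volunteer summary table:
#' the mean and sample SD across subjects of the per-subject means, and the
#' mean and sample SD of the per-subject SDs. Values are kept at full
#' precision; rounding to one decimal happens only in [format()]/[print()]
#' via [round_report()].
#'
#' @param means Numeric vector of per-subject means (n >= 2).
#' @param sds Numeric vector of per-subject SDs (same length).
#' @return A list of class `cohort_summary`: `mean_total`, `sd_total`,
#'   `mean_of_sds`, `sd_of_sds`, `n`.
#' @export
cohort_summary <- function(means, sds) {
  if (length(means) < 2L) {
    bt_abort("undefined_metric", "cohort summary needs >= 2 subjects")
  }
  if (length(sds) != length(means)) {
    bt_abort("validation_error", "means and sds must have equal length")
  }
  structure(list(
    mean_total = mean(means), sd_total = stats::sd(means),
    mean_of_sds = mean(sds), sd_of_sds = stats::sd(sds),
    n = length(means)
  ), class = "cohort_summary")
}

#' @export
format.cohort_summary <- function(x, digits = 1, ...) {
  c(mean_total = sprintf("%.*f ± %.*f", digits,
                         round_report(x$mean_total, digits), digits,
                         round_report(x$sd_total, digits)),
    mean_sd = sprintf("%.*f ± %.*f", digits,
                      round_report(x$mean_of_sds, digits), digits,
                      round_report(x$sd_of_sds, digits)))
}

#' @export
print.cohort_summary <- function(x, ...) {
  f <- format(x, ...)
  cat(sprintf("<cohort_summary> n = %d\n  mean total: %s\n  mean SD:    %s\n",
              x$n, f[["mean_total"]], f[["mean_sd"]]))
  invisible(x)
}

#' Presentation rounding (half away from zero)
#'
#' Rounds to `digits` decimals with halves rounded away from zero, guarded
#' against binary floating-point representation (so e.g. a mean of exactly
#' 10.95 prints as 11.0, not 10.9). Used only at the presentation layer;
#' all statistics are computed at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_report <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Compare two measurement scenarios
#'
#' Applies the study's statistical decision rule: Shapiro-Wilk normality on
#' both groups; when both are compatible with normality (p > 0.05) a paired
#' t-test is used, otherwise a Mann-Whitney U test. An unpaired t-test mode
#' is available via `paired = FALSE`.
#'
#' @param group_a,group_b Numeric vectors of paired per-subject values.
#' @param paired Use the paired t-test branch (default) or an independent
#'   t-test when normality holds.
#' @return A list: `test` (`"paired_t"`, `"independent_t"` or
#'   `"mann_whitney_u"`), `p_value`, `normality_p` (length 2).
#' @export
compare_scenarios <- function(group_a, group_b, paired = TRUE) {
  if (length(group_a) < 3L || length(group_b) < 3L) {
    bt_abort("validation_error", "need n >= 3 per group")
  }
  if (paired && length(group_a) != length(group_b)) {
    bt_abort("validation_error", "paired comparison needs equal lengths")
  }
  sw_a <- stats::shapiro.test(group_a)$p.value
  sw_b <- stats::shapiro.test(group_b)$p.value
  if (sw_a > 0.05 && sw_b > 0.05) {
    if (paired) {
      d <- group_a - group_b
      if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
        bt_abort("degenerate_test",
                 "zero variance in paired differences; t-test undefined")
      }
      ht <- tryCatch(stats::t.test(group_a, group_b, paired = TRUE),
                     error = function(e) bt_abort("degenerate_test",
                                                  conditionMessage(e)))
      test <- "paired_t"
    } else {
      ht <- stats::t.test(group_a, group_b, paired = FALSE)
      test <- "independent_t"
    }
  } else {
    ht <- suppressWarnings(stats::wilcox.test(group_a, group_b, paired = FALSE))
    test <- "mann_whitney_u"
  }
  list(test = test, p_value = unname(ht$p.value),
       normality_p = c(a = sw_a, b = sw_b))
}
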