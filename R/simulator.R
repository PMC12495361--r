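# Synthetic test bed for the full pipeline: breathing patterns, load-
# dependent couch sag, camera pitch embedding, X-ray scheduling and
# isotropic tracking noise. Stands in for the optical tracker, the couch
# and the scanner so that every claim about the correction can be checked
# against a known ground truth.

#' Simulation configuration
#'
#' Collects every knob of the synthetic session. Defaults reproduce the
#' phantom 4DCT protocol: sinusoidal breathing at 0.2 Hz with 20 mm
#' peak-to-trough amplitude, worst-case couch sag of -5 mm developing during
#' table travel, 0.06 mm RMS tracking noise per axis and a 16.6 ms constant
#' latency on the table stream.
#'
#' @param pattern `"sinusoid"`, `"cos6"` or `"dibh_sequence"`.
#' @param amplitude Peak-to-trough breathing amplitude, mm.
#' @param frequency Sinusoid frequency, Hz.
#' @param T cos^6 cycle duration, s.
#' @param exponent cos-power exponent for the `"cos6"` pattern.
#' @param plateau_duration Breath-hold flat-top duration, s.
#' @param n_plateaus Number of breath-holds in a DIBH sequence.
#' @param free_amplitude Peak-to-trough amplitude of the free-breathing
#'   baseline between breath-holds, mm.
#' @param ramp_s Linear inhale/exhale ramp into and out of each hold, s.
#' @param lead_in_s Free breathing before the first hold, s.
#' @param gap_s Free breathing between holds, s.
#' @param scan_mode `"helical_dibh"` (one beam-on block, sag develops over
#'   it) or `"axial_4dct"` (repeated beam-on blocks separated by table-feed
#'   gaps; sag develops stepwise during the gaps).
#' @param scan_start_s Time of the first beam-on sample, s.
#' @param beam_on_s Axial beam-on block duration, s.
#' @param feed_gap_s Gap between axial blocks (table feed), s.
#' @param n_blocks Number of axial beam-on blocks.
#' @param sag_max Worst-case couch deflection, mm (<= 0; anterior positive
#'   convention, so sag is negative).
#' @param load Scenario load label in kg: one of 0, 52, 104, scaling the
#'   deflection to 20%, 60% and 100% of `sag_max`.
#' @param table_feed Axial table feed per step, mm (recorded for provenance;
#'   longitudinal motion does not enter the AP channel).
#' @param pitch_theta Camera pitch angle, radians.
#' @param noise_rms Tracking noise RMS per global axis, mm.
#' @param latency Constant latency of the table stream, s.
#' @param sample_rate Sampling rate, Hz.
#' @param duration Session length, s.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pattern = c("sinusoid", "cos6", "dibh_sequence"),
                       amplitude = 20, frequency = 0.2, T = 10, exponent = 6,
                       plateau_duration = 6.5, n_plateaus = 3,
                       free_amplitude = 10, ramp_s = 1, lead_in_s = 10,
                       gap_s = 8,
                       scan_mode = c("axial_4dct", "helical_dibh"),
                       scan_start_s = 8, beam_on_s = 6, feed_gap_s = 2,
                       n_blocks = 5,
                       sag_max = -5, load = 104, table_feed = 34.5,
                       pitch_theta = 0.35, noise_rms = 0.06,
                       latency = 0.0166, sample_rate = 50, duration = 60,
                       seed = 1L) {
  pattern <- match.arg(pattern)
  scan_mode <- match.arg(scan_mode)
  if (!load %in% c(0, 52, 104)) {
    bt_abort("config_error", "load must be one of 0, 52, 104 (kg)")
  }
  if (sag_max > 0) bt_abort("config_error", "sag_max must be <= 0 mm")
  if (noise_rms < 0) bt_abort("config_error", "noise_rms must be >= 0")
  f_breath <- if (pattern == "cos6") 1 / T else frequency
  if (sample_rate <= 2 * f_breath) {
    bt_abort("config_error", "sample_rate must exceed twice the breathing frequency")
  }
  structure(list(
    pattern = pattern, amplitude = amplitude, frequency = frequency, T = T,
    exponent = exponent, plateau_duration = plateau_duration,
    n_plateaus = n_plateaus, free_amplitude = free_amplitude,
    ramp_s = ramp_s, lead_in_s = lead_in_s, gap_s = gap_s,
    scan_mode = scan_mode, scan_start_s = scan_start_s,
    beam_on_s = beam_on_s, feed_gap_s = feed_gap_s, n_blocks = n_blocks,
    sag_max = sag_max, load = load, table_feed = table_feed,
    pitch_theta = pitch_theta, noise_rms = noise_rms, latency = latency,
    sample_rate = sample_rate, duration = duration, seed = as.integer(seed)
  ), class = "sim_config")
}

# Fraction of sag_max realised under each scenario load.
sag_scale <- function(load) c(`0` = 0.2, `52` = 0.6, `104` = 1.0)[[as.character(load)]]

# Smoothstep ramp 3u^2 - 2u^3 on [0, 1], clamped outside.
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' X-ray / table-travel schedule implied by a configuration
#'
#' Helical mode yields a single beam-on block; axial 4DCT mode yields
#' `n_blocks` blocks of `beam_on_s` separated by `feed_gap_s` table-feed
#' gaps. In the DIBH sequence the helical block covers the flat top of the
#' final breath-hold.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `t_on`, `t_off`.
#' @export
xray_schedule <- function(config) {
  if (config$scan_mode == "axial_4dct") {
    t_on <- config$scan_start_s +
      (seq_len(config$n_blocks) - 1L) * (config$beam_on_s + config$feed_gap_s)
    return(data.frame(t_on = t_on, t_off = t_on + config$beam_on_s))
  }
  if (config$pattern == "dibh_sequence") {
    st <- dibh_schedule(config)
    i <- nrow(st)
    return(data.frame(t_on = st$flat_start[i], t_off = st$flat_end[i]))
  }
  data.frame(t_on = 0.25 * config$duration, t_off = 0.75 * config$duration)
}

# Hold timing for the DIBH sequence: ramp/flat interval per plateau.
dibh_schedule <- function(config) {
  block <- 2 * config$ramp_s + config$plateau_duration + config$gap_s
  start <- config$lead_in_s + (seq_len(config$n_plateaus) - 1L) * block
  data.frame(
    ramp_up_start = start,
    flat_start = start + config$ramp_s,
    flat_end = start + config$ramp_s + config$plateau_duration,
    ramp_down_end = start + 2 * config$ramp_s + config$plateau_duration
  )
}

#' True breathing displacement at time t
#'
#' `"sinusoid"`: `(A/2) * (1 - cos(2 pi f t))`, range `[0, A]`.
#' `"cos6"`: the guidance waveform shared with the feedback module.
#' `"dibh_sequence"`: free-breathing sinusoid interleaved with
#' `n_plateaus` breath-holds at level `amplitude`, entered and left through
#' linear ramps of `ramp_s`.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param config A [sim_config()].
#' @return Displacement(s) in mm.
#' @export
breathing_pattern <- function(t, config) {
  A <- config$amplitude
  base <- function(tt) (config$free_amplitude / 2) *
    (1 - cos(2 * pi * config$frequency * tt))
  switch(config$pattern,
    sinusoid = (A / 2) * (1 - cos(2 * pi * config$frequency * t)),
    cos6 = guidance_waveform(
      t, guidance_params(A = A, T = config$T, exponent = config$exponent)),
    dibh_sequence = {
      x <- base(t)
      st <- dibh_schedule(config)
      for (i in seq_len(nrow(st))) {
        r0 <- st$ramp_up_start[i]; f0 <- st$flat_start[i]
        f1 <- st$flat_end[i]; r1 <- st$ramp_down_end[i]
        up <- t >= r0 & t < f0
        x[up] <- base(r0) + (A - base(r0)) * (t[up] - r0) / config$ramp_s
        x[t >= f0 & t <= f1] <- A
        dn <- t > f1 & t <= r1
        x[dn] <- A + (base(r1) - A) * (t[dn] - f1) / config$ramp_s
      }
      x
    },
    bt_abort("config_error", sprintf("unknown pattern '%s'", config$pattern))
  )
}

#' True couch deflection at time t
#'
#' Zero before the first beam-on event; during table travel the couch
#' deflects along a smoothstep time-course to
#' `sag_scale(load) * sag_max` (scales 0.2 / 0.6 / 1.0 for 0 / 52 / 104 kg).
#' Helical mode deflects over the single beam-on block; axial mode adds an
#' equal smoothstep increment during every table-feed gap between blocks.
#' The same deflection rides under both markers.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param config A [sim_config()].
#' @return Deflection(s) in mm (<= 0).
#' @export
sag_profile <- function(t, config) {
  total <- sag_scale(config$load) * config$sag_max
  if (total == 0) return(rep(0, length(t)))
  ev <- xray_schedule(config)
  if (config$scan_mode == "helical_dibh" || nrow(ev) == 1L) {
    return(total * smoothstep((t - ev$t_on[1]) / (ev$t_off[1] - ev$t_on[1])))
  }
  # axial: deflection accrues during the gaps between consecutive blocks
  n_gaps <- nrow(ev) - 1L
  inc <- total / n_gaps
  out <- rep(0, length(t))
  for (k in seq_len(n_gaps)) {
    g0 <- ev$t_off[k]; g1 <- ev$t_on[k + 1L]
    out <- out + inc * smoothstep((t - g0) / (g1 - g0))
  }
  out
}

#' Run a synthetic tracking session
#'
#' Generates the two marker pose streams a ceiling-mounted tracker would
#' record: the patient marker carries breathing plus couch sag on its AP
#' channel, the table marker carries sag alone, both embedded into global
#' camera coordinates through the inverse pitch rotation, with seeded
#' isotropic Gaussian noise per global axis. The table stream is sampled on
#' a grid delayed by the configured latency. Ground truth (breathing, sag,
#' X-ray schedule) is returned alongside.
#'
#' @param config A [sim_config()].
#' @return A list of class `bt_simulation`: `patient_log`, `table_log`
#'   (pose-log data frames), `truth` (list `t`, `breathing`, `sag`,
#'   `xray`), and `config`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  t <- seq(0, config$duration, by = 1 / config$sample_rate)
  n <- length(t)
  breathing <- breathing_pattern(t, config)
  sag_p <- sag_profile(t, config)
  t_table <- t + config$latency
  sag_t <- sag_profile(t_table, config)

  # patient-frame AP channels; ML/CC offsets are arbitrary static positions
  patient_ap <- breathing + sag_p
  table_ap <- sag_t
  noise_p <- matrix(stats::rnorm(3 * n, sd = config$noise_rms), ncol = 3)
  noise_t <- matrix(stats::rnorm(3 * n, sd = config$noise_rms), ncol = 3)

  Rt <- t(pitch_matrix(config$pitch_theta))  # patient -> global
  embed <- function(ap, ml, cc, noise) {
    v <- cbind(ap, ml, cc) %*% t(Rt)  # rows: global positions
    v + noise
  }
  gp <- embed(patient_ap, 50, 300, noise_p)
  gt <- embed(table_ap, -200, 300, noise_t)

  R <- pitch_matrix(config$pitch_theta)
  rot <- as.vector(t(R))  # m11 m12 m13 m21 ... m33, row-major
  make_log <- function(ts, g, marker) {
    data.frame(
      t_s = ts, marker_id = marker,
      m11 = rot[1], m12 = rot[2], m13 = rot[3], m14 = g[, 1],
      m21 = rot[4], m22 = rot[5], m23 = rot[6], m24 = g[, 2],
      m31 = rot[7], m32 = rot[8], m33 = rot[9], m34 = g[, 3],
      stringsAsFactors = FALSE
    )[, POSE_COLS]
  }
  structure(list(
    patient_log = make_log(t, gp, "patient"),
    table_log = make_log(t_table, gt, "table"),
    truth = list(t = t, breathing = breathing, sag = sag_p,
                 xray = xray_schedule(config)),
    config = config
  ), class = "bt_simulation")
}

#' Apply the table-motion correction to a simulated or recorded session
#'
#' Estimates the session pitch from the table marker stream, projects both
#' streams onto the patient AP axis, pairs them in time and subtracts the
#' table signal. Returns corrected and uncorrected breathing traces with
#' X-ray flags applied from the event list.
#'
#' @param patient_log,table_log Pose-log data frames (one marker each), or
#'   pass a `bt_simulation` as `patient_log` to use its streams and truth
#'   events directly.
#' @param events Optional data frame `t_on`, `t_off` of beam-on events.
#' @param max_gap Maximum pairing gap in seconds (see [pair_streams()]).
#' @param theta Session pitch override (radians); estimated when `NULL`.
#' @return A list: `corrected` and `uncorrected` [breathing_trace()]s,
#'   `theta`.
#' @export
correct_session <- function(patient_log, table_log = NULL, events = NULL,
                            max_gap = 0.2, theta = NULL) {
  if (inherits(patient_log, "bt_simulation")) {
    sim <- patient_log
    table_log <- sim$table_log
    events <- events %||% sim$truth$xray
    patient_log <- sim$patient_log
  }
  if (is.null(table_log)) {
    bt_abort("validation_error", "table marker stream is required")
  }
  if (is.null(theta)) theta <- estimate_pitch(table_log, marker = "table")
  pat <- project_pose_log(patient_log, "patient", theta)
  tab <- project_pose_log(table_log, "table", theta)
  paired <- pair_streams(pat, tab, max_gap = max_gap)
  flags <- flags_from_events(paired$t, events)
  list(
    corrected = breathing_trace(paired$t, paired$x_corrected, flags,
                                label = "corrected"),
    uncorrected = breathing_trace(paired$t, paired$x_breathing, flags,
                                  label = "uncorrected"),
    theta = theta
  )
}

# TRUE where t falls inside any [t_on, t_off) event.
flags_from_events <- function(t, events) {
  if (is.null(events) || nrow(events) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (k in seq_len(nrow(events))) {
    out <- out | (t >= events$t_on[k] & t < events$t_off[k])
  }
  out
}

#' Named scenario presets
#'
#' Twelve ready-made configurations mirroring the study conditions: the
#' phantom 3 x 2 grid (DIBH / 4DCT under 0, +52, +104 kg couch load, worst
#' case deflection -5 mm, sinusoid 0.2 Hz / 20 mm, 6.5 s breath-holds) and
#' the volunteer scenarios (audio guidance, visual guidance, visual guidance
#' with table travel; 4DCT guidance cos^6 with A = 30 mm, T = 10 s over
#' 30 s). Volunteer "table movement" presets reproduce a clinically typical
#' deflection of -1.7 mm; the no-movement presets have zero sag.
#'
#' @return Named list of [sim_config()] objects.
#' @export
scenario_presets <- function() {
  p <- list()
  for (load in c(0, 52, 104)) {
    p[[sprintf("phantom_dibh_%dkg", load)]] <- sim_config(
      pattern = "dibh_sequence", amplitude = 20, frequency = 0.2,
      plateau_duration = 6.5, n_plateaus = 3,
      scan_mode = "helical_dibh", sag_max = -5, load = load,
      sample_rate = 50, duration = 60, seed = 1L)
    p[[sprintf("phantom_4dct_%dkg", load)]] <- sim_config(
      pattern = "sinusoid", amplitude = 20, frequency = 0.2,
      scan_mode = "axial_4dct", sag_max = -5, load = load,
      sample_rate = 50, duration = 60, seed = 1L)
  }
  vol_dibh <- function(sag) sim_config(
    pattern = "dibh_sequence", amplitude = 15, frequency = 0.25,
    plateau_duration = 6, n_plateaus = 3, scan_mode = "helical_dibh",
    sag_max = sag, load = 104, sample_rate = 50, duration = 60, seed = 1L)
  vol_4dct <- function(pattern, sag) sim_config(
    pattern = pattern, amplitude = if (pattern == "cos6") 30 else 16,
    frequency = 0.2, T = 10, scan_mode = "axial_4dct",
    scan_start_s = 4, beam_on_s = 4, feed_gap_s = 2, n_blocks = 4,
    sag_max = sag, load = 104, sample_rate = 50, duration = 30, seed = 1L)
  p[["volunteer_dibh_audio"]] <- vol_dibh(0)
  p[["volunteer_dibh_visual"]] <- vol_dibh(0)
  p[["volunteer_dibh_visual_table"]] <- vol_dibh(-1.7)
  p[["volunteer_4dct_audio"]] <- vol_4dct("sinusoid", 0)
  p[["volunteer_4dct_visual"]] <- vol_4dct("cos6", 0)
  p[["volunteer_4dct_visual_table"]] <- vol_4dct("cos6", -1.7)
  p
}

#' Fetch one preset configuration by name
#'
#' @param name Preset name (see [scenario_presets()]).
#' @param seed Optional seed override.
#' @return A [sim_config()].
#' @export
preset_config <- function(name, seed = NULL) {
  p <- scenario_presets()
  if (!name %in% names(p)) {
    bt_abort("usage_error", sprintf(
      "unknown preset '%s'; available: %s", name,
      paste(names(p), collapse = ", ")))
  }
  cfg <- p[[name]]
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}
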