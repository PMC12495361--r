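# File formats and stream pairing.
#
# Trace CSV:  header `t_s,amplitude_mm,xray_on`, comma separated, '.' decimal,
#             xray_on encoded 0/1. Amplitudes are written at full double
#             precision (%.17g) so write -> read round-trips bit-exactly.
# Pose log:   header `t_s,marker_id,m11,m12,m13,m14,m21,...,m34`; the twelve
#             m-values are the upper 3x4 block of the homogeneous transform,
#             row-major, translations (m14, m24, m34) in mm.

POSE_COLS <- c("t_s", "marker_id",
               "m11", "m12", "m13", "m14",
               "m21", "m22", "m23", "m24",
               "m31", "m32", "m33", "m34")

#' Read a breathing trace from CSV
#'
#' @param path Path to a trace CSV with header `t_s,amplitude_mm,xray_on`.
#' @param label Optional label; defaults to the file name.
#' @return A [breathing_trace()].
#' @export
read_trace <- function(path, label = NULL) {
  if (!file.exists(path)) {
    bt_abort("parse_error", sprintf("trace file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  skip <- 0L  # leading '#' lines carry provenance (seed, parameters)
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#")) skip <- skip + 1L
  if (length(lines) <= skip ||
      gsub("\\s", "", lines[skip + 1L]) != "t_s,amplitude_mm,xray_on") {
    bt_abort("parse_error",
             sprintf("%s: expected header 't_s,amplitude_mm,xray_on'", path))
  }
  body <- lines[-seq_len(skip + 1L)]
  line_no <- which(nzchar(trimws(body))) + skip + 1L
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  t <- numeric(n); amp <- numeric(n); flag <- logical(n)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 3L || any(is.na(vals))) {
      bt_abort("parse_error",
               sprintf("%s: malformed row at line %d: '%s'", path, line_no[i], body[i]))
    }
    if (!vals[3] %in% c(0, 1)) {
      bt_abort("parse_error",
               sprintf("%s: xray flag must be 0/1 at line %d", path, line_no[i]))
    }
    t[i] <- vals[1]; amp[i] <- vals[2]; flag[i] <- vals[3] == 1
  }
  if (n >= 2L && any(diff(t) <= 0)) {
    bt_abort("validation_error",
             sprintf("%s: timestamps must be strictly increasing", path))
  }
  breathing_trace(t, amp, flag, label = label %||% basename(path))
}

#' Write a breathing trace to CSV
#'
#' @param trace A [breathing_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "breathing_trace"))
  s <- trace$samples
  lines <- c("t_s,amplitude_mm,xray_on",
             sprintf("%.17g,%.17g,%d", s$t, s$amplitude, as.integer(s$xray_on)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dual-marker pose log
#'
#' @param path Path to a pose-log CSV (see package file-format docs).
#' @return A data frame with columns `t_s`, `marker_id`, `m11` .. `m34`.
#' @export
read_pose_log <- function(path) {
  if (!file.exists(path)) {
    bt_abort("parse_error", sprintf("pose log not found: %s", path))
  }
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  skip <- 0L
  while (skip < length(head_lines) && startsWith(head_lines[skip + 1L], "#")) {
    skip <- skip + 1L
  }
  if (length(head_lines) <= skip ||
      gsub("\\s", "", head_lines[skip + 1L]) != paste(POSE_COLS, collapse = ",")) {
    bt_abort("parse_error", sprintf("%s: unexpected pose-log header", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, skip = skip)
  num <- setdiff(POSE_COLS, "marker_id")
  for (cn in num) {
    if (!is.numeric(df[[cn]]) || anyNA(df[[cn]])) {
      bt_abort("parse_error", sprintf("%s: non-numeric values in %s", path, cn))
    }
  }
  if (!all(df$marker_id %in% c("patient", "table"))) {
    bt_abort("parse_error", sprintf("%s: marker_id must be patient/table", path))
  }
  df
}

#' Write a pose log
#'
#' @param pose_log Data frame with the pose-log columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_log <- function(pose_log, path) {
  stopifnot(all(POSE_COLS %in% names(pose_log)))
  df <- pose_log[, POSE_COLS]
  num <- setdiff(POSE_COLS, "marker_id")
  rows <- do.call(sprintf, c(
    list(fmt = paste0("%.17g,%s,", paste(rep("%.17g", 12), collapse = ","))),
    list(df$t_s, df$marker_id),
    lapply(num[-1], function(cn) df[[cn]])
  ))
  writeLines(c(paste(POSE_COLS, collapse = ","), rows), path)
  invisible(path)
}

#' Project a pose-log marker stream onto the patient AP axis
#'
#' @param pose_log Pose-log data frame.
#' @param marker `"patient"` or `"table"`.
#' @param theta Session pitch angle (radians), e.g. from [estimate_pitch()].
#' @return Data frame with columns `t` (s) and `x_ap` (mm).
#' @export
project_pose_log <- function(pose_log, marker, theta) {
  rows <- pose_log[pose_log$marker_id == marker, , drop = FALSE]
  if (nrow(rows) == 0L) {
    bt_abort("validation_error", sprintf("no '%s' frames in pose log", marker))
  }
  v <- cbind(rows$m14, rows$m24, rows$m34)
  data.frame(t = rows$t_s, x_ap = project_ap(v, theta))
}

#' Pair an asynchronous table stream with the patient stream
#'
#' Linearly interpolates the table AP series onto the patient timestamps.
#' Patient samples outside the table stream's time range, or whose nearest
#' table frame is farther than `max_gap`, are dropped.
#'
#' @param patient Data frame `t`, `x_ap` for the patient marker.
#' @param table Data frame `t`, `x_ap` for the table marker.
#' @param max_gap Maximum tolerated distance (s) to the nearest table frame.
#' @return Data frame `t`, `x_breathing`, `x_table`, `x_corrected`.
#' @export
pair_streams <- function(patient, table, max_gap = 0.2) {
  if (nrow(patient) == 0L || nrow(table) == 0L) {
    bt_abort("validation_error", "both streams must be non-empty")
  }
  if (any(diff(patient$t) <= 0) || any(diff(table$t) <= 0)) {
    bt_abort("validation_error", "stream timestamps must be strictly increasing")
  }
  lo <- max(patient$t[1], table$t[1])
  hi <- min(patient$t[nrow(patient)], table$t[nrow(table)])
  if (lo > hi) {
    bt_abort("empty_overlap", "patient and table streams do not overlap in time")
  }
  keep <- patient$t >= lo & patient$t <= hi
  tp <- patient$t[keep]
  # distance to nearest table frame (table$t sorted)
  idx <- findInterval(tp, table$t)
  d_left <- ifelse(idx >= 1L, tp - table$t[pmax(idx, 1L)], Inf)
  d_right <- ifelse(idx < nrow(table), table$t[pmin(idx + 1L, nrow(table))] - tp, Inf)
  near <- pmin(d_left, d_right)
  keep2 <- near <= max_gap
  tp <- tp[keep2]
  if (length(tp) == 0L) {
    bt_abort("empty_overlap", "no patient samples within max_gap of table frames")
  }
  xt <- stats::approx(table$t, table$x_ap, xout = tp, method = "linear")$y
  xb <- patient$x_ap[keep][keep2]
  data.frame(t = tp, x_breathing = xb, x_table = xt,
             x_corrected = correct_breathing(xb, xt))
}

#' Align traces at their first X-ray-on transition
#'
#' Each trace is shifted in time so that its first off-to-on transition sits
#' at `t = 0`; amplitudes are untouched. Idempotent.
#'
#' @param traces A list of [breathing_trace()] objects (or a single trace).
#' @return The shifted trace(s), same shape as the input.
#' @export
align_first_xray <- function(traces) {
  single <- inherits(traces, "breathing_trace")
  if (single) traces <- list(traces)
  out <- lapply(traces, function(tr) {
    s <- tr$samples
    on <- s$xray_on
    if (!any(on)) {
      bt_abort("alignment_error",
               sprintf("trace '%s' has no X-ray-on samples", tr$label))
    }
    trans <- which(on & !c(FALSE, utils::head(on, -1)))[1]
    breathing_trace(s$t - s$t[trans], s$amplitude, s$xray_on,
                    label = tr$label, sample_rate_hz = tr$sample_rate_hz)
  })
  if (single) out[[1]] else out
}

#' Extract X-ray beam-on events from a trace
#'
#' Maximal runs of `xray_on` samples are reported as events; `t_on` is the
#' time of the first on-sample, `t_off` the time of the first off-sample
#' after the run (or the last timestamp if the trace ends beam-on).
#'
#' @param trace A [breathing_trace()].
#' @return Data frame with columns `t_on`, `t_off` (possibly 0 rows).
#' @export
extract_xray_events <- function(trace) {
  s <- trace$samples
  on <- s$xray_on
  if (!any(on)) return(data.frame(t_on = numeric(0), t_off = numeric(0)))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_runs <- which(r$values)
  t_on <- s$t[starts[on_runs]]
  t_off <- vapply(on_runs, function(k) {
    if (ends[k] < nrow(s)) s$t[ends[k] + 1L] else s$t[nrow(s)]
  }, numeric(1))
  data.frame(t_on = t_on, t_off = t_off)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
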