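# Marker-pose geometry: camera pitch extraction and the global -> patient
# anterior-posterior projection, plus the subtraction that removes table
# motion from the patient signal.
#
# Convention (fixed package-wide): the y-axis pitch matrix
#
#   P(theta) = [ cos(theta) 0 sin(theta);
#                0          1 0;
#               -sin(theta) 0 cos(theta) ]
#
# maps GLOBAL (camera) coordinates to PATIENT coordinates
# (anterior-posterior, medial-lateral, cranial-caudal). The tracker reports
# each marker's orientation as this same matrix, whose (3,1) element is
# -sin(theta), so theta = asin(-R31). compose_pose() therefore stores
# P(theta) as the pose rotation and extract_pitch() inverts it exactly;
# positions are embedded into global coordinates with t(P(theta)).

#' Y-axis pitch rotation matrix (global to patient frame)
#'
#' @param theta Pitch angle in radians, `|theta| < pi/2`.
#' @return A 3x3 rotation matrix mapping global (camera) coordinates to
#'   patient coordinates (AP, ML, CC).
#' @export
pitch_matrix <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L)
  bt_stopifnot_finite(theta, "theta")
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, s_,
           0, 1, 0,
           -s_, 0, c_), nrow = 3, byrow = TRUE)
}

#' Build a marker pose from a pitch angle and a translation
#'
#' Constructs a time-stamped 4x4 homogeneous transform whose rotation block
#' is the y-axis pitch matrix (so that [extract_pitch()] round-trips) and
#' whose translation is stored verbatim, in mm.
#'
#' @param theta Pitch angle in radians, `|theta| < pi/2`.
#' @param translation Numeric length-3 global translation (mm).
#' @param t Timestamp in seconds.
#' @param marker_id `"patient"` or `"table"`.
#' @return An object of class `bt_pose` with fields `t`, `marker_id`, `M`.
#' @export
compose_pose <- function(theta, translation = c(0, 0, 0), t = 0,
                         marker_id = c("patient", "table")) {
  marker_id <- match.arg(marker_id)
  stopifnot(length(translation) == 3L)
  if (!is.finite(theta) || abs(theta) >= pi / 2) {
    bt_abort("validation_error", "theta must be finite with |theta| < pi/2")
  }
  bt_stopifnot_finite(translation, "translation")
  M <- diag(4)
  M[1:3, 1:3] <- pitch_matrix(theta)
  M[1:3, 4] <- translation
  structure(list(t = t, marker_id = marker_id, M = M), class = "bt_pose")
}

# Orthonormality check for a pose rotation block; tolerance 1e-6 per the
# package contract (bad poses are rejected, never repaired).
validate_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !all(is.finite(R))) {
    bt_abort("invalid_rotation", "rotation block must be a finite 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    bt_abort("invalid_rotation",
             sprintf("rotation block not orthonormal within %g", tol))
  }
  if (abs(det(R) - 1) > tol) {
    bt_abort("invalid_rotation", "rotation block must be proper (det = +1)")
  }
  invisible(R)
}

#' Extract the camera pitch angle from a marker pose
#'
#' The pitch is read from the (3,1) element of the pose's orientation
#' matrix as `theta = asin(-R31)` (principal branch).
#'
#' @param pose A `bt_pose` (see [compose_pose()]) or a 4x4/3x3 matrix.
#' @return Pitch angle in radians.
#' @export
extract_pitch <- function(pose) {
  M <- if (inherits(pose, "bt_pose")) pose$M else pose
  if (!is.matrix(M)) bt_abort("invalid_rotation", "pose must carry a matrix")
  R <- M[1:3, 1:3]
  validate_rotation(R)
  r31 <- R[3, 1]
  if (abs(r31) > 1 + 1e-9) {
    bt_abort("invalid_rotation", "|R31| > 1: not a valid rotation")
  }
  asin(-max(-1, min(1, r31)))
}

#' Rotate a global vector into the patient frame
#'
#' Applies the y-axis pitch rotation, returning
#' (anterior-posterior, medial-lateral, cranial-caudal) in mm.
#'
#' @param v_global Numeric length-3 global vector (mm).
#' @param theta Pitch angle in radians.
#' @export
rotate_to_patient <- function(v_global, theta) {
  stopifnot(length(v_global) == 3L)
  bt_stopifnot_finite(v_global, "v_global")
  drop(pitch_matrix(theta) %*% v_global)
}

#' Project a global position onto the patient anterior-posterior axis
#'
#' Computes `x_global * cos(theta) + z_global * sin(theta)`, i.e. the first
#' component of [rotate_to_patient()]. Vectorised over positions.
#'
#' @param v_global Length-3 vector, or an n x 3 matrix of positions (mm).
#' @param theta Pitch angle in radians.
#' @return AP displacement(s) in mm.
#' @export
project_ap <- function(v_global, theta) {
  bt_stopifnot_finite(theta, "theta")
  if (is.matrix(v_global)) {
    bt_stopifnot_finite(v_global, "v_global")
    return(v_global[, 1] * cos(theta) + v_global[, 3] * sin(theta))
  }
  stopifnot(length(v_global) == 3L)
  bt_stopifnot_finite(v_global, "v_global")
  v_global[1] * cos(theta) + v_global[3] * sin(theta)
}

#' Subtract table motion from the patient breathing signal
#'
#' The corrected breathing motion is the exact sample-wise difference
#' `x_breathing - x_table`; no smoothing or scaling is applied.
#'
#' @param x_breathing Patient AP displacement(s), mm.
#' @param x_table Table AP displacement(s), mm.
#' @return Corrected AP breathing displacement(s), mm.
#' @export
correct_breathing <- function(x_breathing, x_table) {
  bt_stopifnot_finite(x_breathing, "x_breathing")
  bt_stopifnot_finite(x_table, "x_table")
  x_breathing - x_table
}

#' Estimate the session pitch angle from a pose log
#'
#' The camera pitch is a property of the room geometry, not of the breathing
#' motion, so it is estimated once per session: the median of per-frame pitch
#' extractions over the first `window_s` seconds of the reference (table)
#' marker stream. Using a single robust estimate avoids injecting per-frame
#' marker-orientation noise into the position correction.
#'
#' @param pose_log A pose-log data frame (see [read_pose_log()]).
#' @param marker Which marker stream to use, default `"table"`.
#' @param window_s Length of the initial window in seconds.
#' @return Estimated pitch angle in radians.
#' @export
estimate_pitch <- function(pose_log, marker = "table", window_s = 1) {
  rows <- pose_log[pose_log$marker_id == marker, , drop = FALSE]
  if (nrow(rows) == 0L) {
    bt_abort("validation_error",
             sprintf("pose log has no '%s' marker frames", marker))
  }
  rows <- rows[rows$t_s <= rows$t_s[1] + window_s, , drop = FALSE]
  thetas <- vapply(seq_len(nrow(rows)), function(i) {
    extract_pitch(pose_row_matrix(rows[i, ]))
  }, numeric(1))
  stats::median(thetas)
}

# Reassemble the 4x4 transform from one pose-log row (m11..m34 row-major,
# translations in the fourth column).
pose_row_matrix <- function(row) {
  M <- diag(4)
  M[1, 1:4] <- as.numeric(row[c("m11", "m12", "m13", "m14")])
  M[2, 1:4] <- as.numeric(row[c("m21", "m22", "m23", "m24")])
  M[3, 1:4] <- as.numeric(row[c("m31", "m32", "m33", "m34")])
  M
}
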