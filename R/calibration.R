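#' Frame alignment and joint angles
#'
#' The fusion stage estimates each sensor's orientation in a z-up Earth
#' frame with arbitrary yaw (no magnetometer). This module (i) matches all
#' sensors' yaw to a reference sensor over the static window and remaps to
#' the analysis Earth convention (x down, y forward, z right), (ii)
#' removes constant sensor-mounting rotations using the static neutral
#' pose, and (iii) computes joint angles from relative segment rotations.
#'
#' @name calibration
NULL

# Fixed remap from the fusion Earth frame (z up) to the analysis Earth
# convention: x down, y forward, z to the right.
EARTH_REMAP <- matrix(c(0, 0, -1,
                        1, 0,  0,
                        0, -1, 0), nrow = 3, byrow = TRUE)

# Heading (rotation about the fusion-frame vertical) of a quaternion.
# Sensors are worn with their x-axis roughly along the segment (vertical
# when standing), so heading is read from the y-axis, which points
# forward and stays close to horizontal in the static pose.
quat_yaw <- function(q) {
  R <- quat_to_rotmat(q)
  atan2(R[2, 2], R[1, 2])
}

#' Align all sensors to a common Earth frame
#'
#' Matches every sensor's yaw (heading about the vertical) to the
#' reference sensor's yaw averaged over the static window, then remaps the
#' Earth frame so its x-axis points downward, y forward and z to the
#' right. Relative segment rotations are invariant to the remap; the yaw
#' matching makes headings comparable across sensors despite the
#' unobservable absolute yaw.
#'
#' @param series named list of [quat_series()], one per placement.
#' @param static_window `c(t0, t1)` of the motionless standing pose, s.
#' @param reference placement used as the heading reference
#'   (default `"thigh_R"`).
#' @return named list of aligned [quat_series()].
#' @export
align_common_frame <- function(series, static_window, reference = "thigh_R") {
  if (!reference %in% names(series))
    stop(sprintf("reference sensor '%s' missing", reference))
  static_mean <- function(s) {
    idx <- which(s$t >= static_window[1] & s$t <= static_window[2])
    if (length(idx) < 2) stop("static window contains too few samples")
    quat_mean(s$q[idx, , drop = FALSE])
  }
  # Pin the convention: during the static stance every sensor's y-axis
  # points forward, so rotating each sensor's static heading to zero both
  # matches all headings to the reference sensor's and anchors "forward"
  # to the stance direction (absolute yaw is unobservable without a
  # magnetometer; subtracting the reference heading from everyone is the
  # same operation).
  q_remap <- rotmat_to_quat(EARTH_REMAP)
  out <- lapply(series, function(s) {
    dyaw <- -quat_yaw(static_mean(s))
    q_fix <- quat_raw_multiply(q_remap, quat_from_axis_angle(c(0, 0, 1), dyaw))
    quat_series(s$t, t(apply(s$q, 1, function(q) {
      quat_normalize(quat_raw_multiply(q_fix, q))
    })))
  })
  names(out) <- names(series)
  out
}

#' Sensor-to-segment calibration offset
#'
#' During the static standing pose all joints are assumed neutral (0 deg),
#' so the segment frame momentarily coincides with the Earth frame up to
#' the constant mounting rotation. The offset is the mean sensor
#' orientation over the window; applying it ([apply_segment_offset()])
#' makes every joint angle average 0 deg over the window and absorbs body
#' curvature / mounting inclination.
#'
#' @param series aligned [quat_series()] for one sensor.
#' @param static_window `c(t0, t1)` in seconds, at least 1 s long.
#' @return unit quaternion offset (sensor orientation at neutral pose).
#' @export
sensor_to_segment_offset <- function(series, static_window) {
  if (diff(static_window) < 1) stop("static window shorter than 1 s")
  idx <- which(series$t >= static_window[1] & series$t <= static_window[2])
  if (length(idx) < 2) stop("static window contains too few samples")
  quat_mean(series$q[idx, , drop = FALSE])
}

#' Apply a sensor-to-segment offset
#'
#' Converts a sensor orientation series into the segment orientation
#' series: q_EB(t) = q_ES(t) * conj(offset).
#'
#' @param series aligned [quat_series()] (sensor to Earth).
#' @param offset quaternion from [sensor_to_segment_offset()].
#' @return [quat_series()] of segment-to-Earth orientations.
#' @export
apply_segment_offset <- function(series, offset) {
  oc <- quat_conjugate(quat_normalize(offset))
  quat_series(series$t, t(apply(series$q, 1, function(q) {
    quat_normalize(quat_raw_multiply(q, oc))
  })))
}

#' Relative rotation between two orientation series
#'
#' R_S1S2(t) = R_ES1(t)^T x R_ES2(t), computed in quaternion form as
#' conj(q1) * q2: the orientation of segment 2 expressed in segment 1's
#' frame.
#'
#' @param s1,s2 [quat_series()] on the same time base.
#' @return [quat_series()] of relative rotations.
#' @export
relative_rotation <- function(s1, s2) {
  if (length(s1$t) != length(s2$t))
    stop("series length mismatch")
  if (max(abs(s1$t - s2$t)) > 1e-9) stop("series time bases differ")
  quat_series(s1$t, t(vapply(seq_along(s1$t), function(k) {
    quat_normalize(quat_raw_multiply(quat_conjugate(s1$q[k, ]), s2$q[k, ]))
  }, numeric(4))))
}

# Intrinsic Z-Y-X Euler angles (radians) of a rotation matrix:
# R = Rz(a) Ry(b) Rx(c). Returns c(a, b, c) and a gimbal flag when the
# middle angle is within `gimbal_tol` of +/-90 deg.
euler_zyx <- function(R, gimbal_tol = 1 * pi / 180) {
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  b <- asin(sb)
  gimbal <- (pi / 2 - abs(b)) < gimbal_tol
  if (!gimbal) {
    a <- atan2(R[2, 1], R[1, 1])
    c <- atan2(R[3, 2], R[3, 3])
  } else {
    a <- atan2(-R[1, 2], R[2, 2])   # convention: fold yaw+roll into a
    c <- 0
  }
  list(angles = c(a, b, c), gimbal = gimbal)
}

# unwrap a radian angle series (remove +/- 2pi jumps)
unwrap_angle <- function(x) {
  d <- diff(x)
  jumps <- round(d / (2 * pi))
  x - c(0, cumsum(jumps)) * 2 * pi
}

#' Joint specifications for the lower-limb sensor chain
#'
#' Pairing of proximal and distal placements per joint, the planes each
#' joint exposes, and the anatomical sign of the flexion axis (knee and
#' ankle flexion rotate the distal segment backward about the
#' mediolateral axis, so their flexion sign is negative in the common
#' frame; flexion is reported positive).
#'
#' @return data frame with one row per joint.
#' @export
joint_specs <- function() {
  data.frame(
    joint = c("ankle_L", "ankle_R", "knee_L", "knee_R", "hip_L", "hip_R"),
    proximal = c("shank_L", "shank_R", "thigh_L", "thigh_R",
                 "back_lower", "back_lower"),
    distal = c("foot_L", "foot_R", "shank_L", "shank_R",
               "thigh_L", "thigh_R"),
    leg = c("L", "R", "L", "R", "L", "R"),
    planes = c("flex_ext", "flex_ext", "flex_ext", "flex_ext",
               "flex_ext;abd_add", "flex_ext;abd_add"),
    flex_sign = c(-1, -1, -1, -1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Joint angles from calibrated segment orientations
#'
#' Euler decomposition (intrinsic Z-Y-X) of the relative rotation between
#' the proximal and distal segment frames. The z-component is reported as
#' flexion/extension (dorsi/plantarflexion at the ankle, flexion positive,
#' fully extended = 0 deg), the y-component as abduction/adduction for the
#' hip. Angles are unwrapped; samples in gimbal proximity (middle Euler
#' angle within 1 deg of +/-90 deg) are flagged and linearly interpolated
#' over.
#'
#' @param proximal,distal calibrated segment [quat_series()].
#' @param joint joint name, a row of [joint_specs()].
#' @return named list of `joint_angles` objects (elements `t`, `angle`
#'   in degrees, `joint`, `plane`, `leg`), one per plane of the joint.
#' @export
joint_angles <- function(proximal, distal, joint) {
  spec <- joint_specs()
  spec <- spec[spec$joint == joint, ]
  if (nrow(spec) != 1L) stop("unknown joint: ", joint)
  rel <- relative_rotation(proximal, distal)
  n <- length(rel$t)
  ang <- matrix(NA_real_, n, 3)
  gimbal <- logical(n)
  for (k in seq_len(n)) {
    e <- euler_zyx(quat_to_rotmat(rel$q[k, ]))
    ang[k, ] <- e$angles
    gimbal[k] <- e$gimbal
  }
  planes <- strsplit(spec$planes, ";")[[1]]
  out <- lapply(planes, function(pl) {
    a <- if (pl == "flex_ext") spec$flex_sign * ang[, 1] else ang[, 2]
    if (any(gimbal) && !all(gimbal)) {
      a[gimbal] <- NA_real_
      a <- stats::approx(rel$t[!is.na(a)], a[!is.na(a)], xout = rel$t,
                         rule = 2)$y
    }
    structure(list(t = rel$t, angle = unwrap_angle(a) * 180 / pi,
                   joint = spec$joint, plane = pl, leg = spec$leg),
              class = "joint_angles")
  })
  names(out) <- planes
  out
}

#' @export
print.joint_angles <- function(x, ...) {
  cat(sprintf("<joint_angles> %s %s: %d samples, range [%.1f, %.1f] deg\n",
              x$joint, x$plane, length(x$t), min(x$angle), max(x$angle)))
  invisible(x)
}
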