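# shared fixture builders; everything is generated in code at test time

GRAV <- 9.81

# static stream for a sensor held at orientation q (sensor -> Earth, z-up)
static_stream <- function(placement = "thigh_R", q = c(1, 0, 0, 0),
                          duration = 3, rate = 200,
                          gyro_sd = 0, accel_sd = 0) {
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  f <- quat_rotate(quat_conjugate(q), c(0, 0, GRAV))
  sensor_stream(placement, t,
                gyro = gyro_sd * matrix(stats::rnorm(3 * n), n, 3),
                accel = matrix(f, n, 3, byrow = TRUE) +
                  accel_sd * matrix(stats::rnorm(3 * n), n, 3),
                rate = rate)
}

# stream following a prescribed orientation path q(t): gyro is the exact
# body-frame angular increment, accel the rotated gravity
stream_from_path <- function(qpath, t, placement = "thigh_R", rate = 200) {
  n <- nrow(qpath)
  gyro <- matrix(0, n, 3)
  accel <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    if (k > 1) {
      dq <- quat_multiply(quat_conjugate(qpath[k - 1, ]), qpath[k, ])
      gyro[k, ] <- quat_log(dq) / (t[k] - t[k - 1])
    }
    accel[k, ] <- quat_rotate(quat_conjugate(qpath[k, ]), c(0, 0, GRAV))
  }
  sensor_stream(placement, t, gyro, accel, rate = rate)
}

# angle (deg) between two unit quaternions
quat_angle_deg <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d)) * 180 / pi
}

# named identity mounts for all placements
identity_mounts <- function() {
  m <- lapply(swim_placements(), function(p) c(1, 0, 0, 0))
  stats::setNames(m, swim_placements())
}

# inclination-dominant random mounts (tilt about sensor y/z, small yaw)
inclination_mounts <- function(tilt_sd = 12, yaw_sd = 3) {
  m <- lapply(swim_placements(), function(p) {
    qt <- quat_from_axis_angle(c(0, stats::rnorm(2)),
                               tilt_sd * pi / 180 * stats::rnorm(1))
    qy <- quat_from_axis_angle(c(1, 0, 0), yaw_sd * pi / 180 * stats::rnorm(1))
    quat_multiply(qt, qy)
  })
  stats::setNames(m, swim_placements())
}

# calibration chain on orientation series (no fusion): align, offset,
# joint angles for the named joints
calibrate_and_angles <- function(q_sensor, static_window,
                                 joints = c("knee_L", "knee_R",
                                            "hip_L", "hip_R")) {
  aligned <- align_common_frame(q_sensor, static_window)
  offs <- lapply(aligned, sensor_to_segment_offset,
                 static_window = static_window)
  segs <- mapply(apply_segment_offset, aligned, offs, SIMPLIFY = FALSE)
  sp <- joint_specs()
  out <- lapply(joints, function(j) {
    row <- sp[sp$joint == j, ]
    joint_angles(segs[[row$proximal]], segs[[row$distal]], j)
  })
  stats::setNames(out, joints)
}

# RMSE of pipeline-estimated flex/ext angles against generator truth,
# over the event-bounded swim window
pipeline_rmse <- function(kin, pipe, joints = c("knee_L", "knee_R",
                                                "hip_L", "hip_R")) {
  vapply(joints, function(j) {
    leg <- sub(".*_", "", j)
    jt <- sub("_.*", "", j)
    est <- pipe$angles[[j]]$flex_ext$angle
    truth <- kin$angles[[leg]][[jt]]$angle
    sel <- kin$t >= kin$events[[leg]]$t[1] &
      kin$t <= max(kin$events[[leg]]$t)
    sqrt(mean((est[sel] - truth[sel])^2))
  }, numeric(1))
}
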