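#' Construct a sensor stream
#'
#' One body placement's synchronized tri-axial gyroscope and accelerometer
#' recording. Gyro in rad/s and accel in m/s^2, both in the sensor frame.
#'
#' @param placement one of `swim_placements()`.
#' @param t time vector in seconds, strictly increasing.
#' @param gyro n x 3 angular velocity matrix, rad/s.
#' @param accel n x 3 specific-force matrix, m/s^2.
#' @param rate nominal sampling rate, Hz (default 200).
#' @return object of class `sensor_stream`.
#' @export
sensor_stream <- function(placement, t, gyro, accel, rate = 200) {
  placement <- match.arg(placement, swim_placements())
  gyro <- rbind(gyro); accel <- rbind(accel)
  stopifnot(rate > 0, length(t) == nrow(gyro), length(t) == nrow(accel),
            ncol(gyro) == 3L, ncol(accel) == 3L)
  if (any(!is.finite(t)) || any(!is.finite(gyro)) || any(!is.finite(accel)))
    stop("non-finite values in sensor stream")
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(dt > 2 / rate))
    stop(sprintf("gap of %.3f s in '%s' stream at t=%.3f s exceeds 2/rate",
                 max(dt), placement, t[which.max(dt)]))
  structure(list(placement = placement, rate = rate, t = t,
                 gyro = gyro, accel = accel),
            class = "sensor_stream")
}

#' Sensor placements used by the toolkit
#'
#' Eight placements: thighs, shanks (above the lateral malleolus), feet,
#' upper back and lower back (sacrum level, used as the pelvis segment).
#'
#' @return character vector of placement names.
#' @export
swim_placements <- function() {
  c("thigh_L", "thigh_R", "shank_L", "shank_R",
    "foot_L", "foot_R", "back_upper", "back_lower")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s: %d samples @ %g Hz, %.2f-%.2f s\n",
              x$placement, length(x$t), x$rate, min(x$t), max(x$t)))
  invisible(x)
}

GRAVITY <- 9.81

#' Initial attitude from a static window
#'
#' Estimates roll and pitch from the mean accelerometer direction over a
#' motionless window (gravity reference); yaw is unobservable without a
#' magnetometer and is set to 0. The window must be genuinely static:
#' gyro RMS above `gyro_rms_max` is a calibration error.
#'
#' @param stream a [sensor_stream()].
#' @param window `c(t0, t1)` in seconds; must cover at least 1 s of data.
#' @param gyro_rms_max motion threshold, rad/s (default 0.1).
#' @return unit quaternion q_ES mapping sensor to Earth (z-up) coordinates.
#' @export
static_attitude_init <- function(stream, window, gyro_rms_max = 0.1) {
  idx <- which(stream$t >= window[1] & stream$t <= window[2])
  if (length(idx) < 2 || diff(range(stream$t[idx])) < 1)
    stop("static window must contain at least 1 s of samples")
  g_rms <- sqrt(mean(stream$gyro[idx, , drop = FALSE]^2) * 3)
  if (g_rms > gyro_rms_max)
    stop(sprintf("motion detected in static window of '%s' (gyro RMS %.3f rad/s)",
                 stream$placement, g_rms))
  a <- colMeans(stream$accel[idx, , drop = FALSE])
  an <- sqrt(sum(a^2))
  if (an == 0) stop("zero mean acceleration in static window")
  a <- a / an                      # measured up direction, sensor frame
  z <- c(0, 0, 1)                  # Earth up
  d <- sum(a * z)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0))  # upside down: 180 deg about x
  axis <- c(a[2] * z[3] - a[3] * z[2],
            a[3] * z[1] - a[1] * z[3],
            a[1] * z[2] - a[2] * z[1])
  quat_from_axis_angle(axis, acos(max(-1, min(1, d))))
}

#' Gravity-referenced attitude estimation (gradient-descent fusion)
#'
#' Madgwick-style 6-axis complementary filter: integrates the gyroscope
#' quaternion rate and corrects toward the accelerometer's gravity
#' direction by a normalized gradient step of size `beta`. With `beta = 0`
#' the filter reduces to pure gyro integration. Samples with a zero-norm
#' accelerometer reading skip the correction (gyro-only update).
#'
#' Per-sample dt is taken from the time vector, so irregular timestamps
#' are handled exactly. `beta_window` allows a larger gain during a static
#' calibration window for fast initial convergence. The accelerometer
#' only measures gravity when the sensor is not accelerating, so the
#' correction is gated: samples whose accel magnitude deviates from 1 g
#' by more than `accel_gate` (propulsion bursts, kicks) get a gyro-only
#' update, and the gravity reference is re-acquired during the quieter
#' glide phases.
#'
#' @param stream a [sensor_stream()].
#' @param beta filter gain, >= 0 (default 0.1; dimension rad/s).
#' @param q0 initial orientation quaternion q_ES (default from
#'   [static_attitude_init()] if `init_window` given, else identity).
#' @param beta_window optional `list(window = c(t0, t1), beta = gain)`
#'   overriding the gain inside the window (default gain 2.0).
#' @param accel_gate accel-magnitude gate half-width, m/s^2 (default 0.3);
#'   `Inf` disables gating.
#' @return a [quat_series()] of sensor-to-Earth quaternions, one per sample.
#' @export
fuse_orientation <- function(stream, beta = 0.1, q0 = c(1, 0, 0, 0),
                             beta_window = NULL, accel_gate = 0.3) {
  stopifnot(beta >= 0, length(stream$t) >= 1)
  q0 <- quat_normalize(q0)
  n <- length(stream$t)
  betas <- rep(beta, n)
  if (!is.null(beta_window)) {
    bw <- if (is.null(beta_window$beta)) 2.0 else beta_window$beta
    betas[stream$t >= beta_window$window[1] &
          stream$t <= beta_window$window[2]] <- bw
  }
  Q <- matrix(0, n, 4)
  q <- q0
  Q[1, ] <- q
  if (n == 1L) return(quat_series(stream$t, Q))
  for (k in 2:n) {
    dt <- stream$t[k] - stream$t[k - 1]
    # exact exponential-map gyro step (reduces to pure integration at beta=0)
    q <- quat_raw_multiply(q, quat_exp(stream$gyro[k, ] * dt))
    a <- stream$accel[k, ]
    an <- sqrt(sum(a^2))
    bk <- betas[k]
    if (an > 0 && bk > 0 && abs(an - GRAVITY) <= accel_gate) {
      a <- a / an
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      # objective: predicted sensor-frame gravity direction minus measured
      f1 <- 2 * (x * z - w * y) - a[1]
      f2 <- 2 * (w * x + y * z) - a[2]
      f3 <- 1 - 2 * (x^2 + y^2) - a[3]
      grad <- c(-2 * y * f1 + 2 * x * f2,
                 2 * z * f1 + 2 * w * f2 - 4 * x * f3,
                -2 * w * f1 + 2 * z * f2 - 4 * y * f3,
                 2 * x * f1 + 2 * y * f2)
      gn <- sqrt(sum(grad^2))
      if (gn > 0) q <- q - bk * dt * grad / gn
    }
    q <- quat_normalize(q)
    Q[k, ] <- q
  }
  quat_series(stream$t, Q)
}

#' Exact gyro-only orientation integration
#'
#' Quaternion-exponential integration of the gyroscope alone (no gravity
#' correction): each step applies exp(omega * dt) in the body frame. This
#' is the reference integrator the fusion filter is checked against at
#' `beta = 0` and the inverse of the synthetic generator's gyro synthesis.
#'
#' @param stream a [sensor_stream()].
#' @param q0 initial unit quaternion.
#' @return a [quat_series()].
#' @export
integrate_gyro <- function(stream, q0 = c(1, 0, 0, 0)) {
  n <- length(stream$t)
  Q <- matrix(0, n, 4)
  q <- quat_normalize(q0)
  Q[1, ] <- q
  if (n > 1) for (k in 2:n) {
    dt <- stream$t[k] - stream$t[k - 1]
    q <- quat_normalize(quat_raw_multiply(q, quat_exp(stream$gyro[k, ] * dt)))
    Q[k, ] <- q
  }
  quat_series(stream$t, Q)
}
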