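#' Quaternion algebra (Hamilton convention, scalar first)
#'
#' Quaternions are length-4 numeric vectors `c(w, x, y, z)`; quaternion
#' series are n x 4 matrices. All rotation quaternions are kept at unit
#' norm; every constructor and operation re-normalizes its result.
#'
#' @name quaternion
NULL

#' Normalize a quaternion to unit norm
#'
#' @param q numeric length-4 `c(w, x, y, z)`.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  stopifnot(length(q) == 4L)
  if (any(!is.finite(q))) stop("non-finite quaternion")
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero-norm quaternion cannot be normalized")
  q / n
}

#' Quaternion conjugate
#' @param q unit quaternion.
#' @return conjugate `c(w, -x, -y, -z)`.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Hamilton product of two quaternions
#'
#' @param a,b unit quaternions (tolerance 1e-6 on the norm).
#' @return the normalized Hamilton product `a %*% b`.
#' @export
quat_multiply <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite quaternion")
  if (abs(sqrt(sum(a^2)) - 1) > 1e-6 || abs(sqrt(sum(b^2)) - 1) > 1e-6)
    stop("quat_multiply expects unit quaternions")
  quat_normalize(quat_raw_multiply(a, b))
}

# Hamilton product without unit-norm checks (internal hot path).
quat_raw_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion from axis-angle
#'
#' @param axis 3-vector rotation axis (any norm > 0).
#' @param angle rotation angle in radians.
#' @return unit quaternion encoding the rotation.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  quat_normalize(c(cos(angle / 2), sin(angle / 2) * axis))
}

#' Rotation matrix from a unit quaternion
#'
#' Returns the proper orthogonal matrix R such that `R %*% v` rotates a
#' vector from the quaternion's source frame into its target frame (for a
#' sensor-to-Earth quaternion q_ES, sensor coordinates to Earth
#' coordinates).
#'
#' @param q unit quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method: picks the numerically largest of the four candidate
#' pivots so the conversion is stable for all rotations.
#'
#' @param R proper orthogonal 3 x 3 matrix.
#' @return unit quaternion with non-negative scalar part.
#' @export
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Rotate a 3-vector by a quaternion
#'
#' @param q unit quaternion.
#' @param v 3-vector in the quaternion's source frame.
#' @return the vector expressed in the target frame.
#' @export
quat_rotate <- function(q, v) {
  p <- quat_raw_multiply(quat_raw_multiply(q, c(0, v)), quat_conjugate(q))
  p[2:4]
}

#' Quaternion exponential map
#'
#' Maps a rotation vector (axis times angle, radians) to its unit
#' quaternion; the basis of exact gyro integration.
#'
#' @param v rotation 3-vector.
#' @return unit quaternion exp(v/2).
#' @export
quat_exp <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-300) return(c(1, 0, 0, 0))
  c(cos(theta / 2), sin(theta / 2) * v / theta)
}

#' Quaternion logarithmic map
#'
#' Inverse of [quat_exp()]: recovers the rotation vector of a unit
#' quaternion.
#'
#' @param q unit quaternion.
#' @return rotation 3-vector (axis times angle, radians).
#' @export
quat_log <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-300) return(c(0, 0, 0))
  theta <- 2 * atan2(vn, q[1])
  theta * q[2:4] / vn
}

# Chordal mean of nearly-parallel unit quaternions (rows of Q), sign-fixed
# against the first row. Adequate for averaging over a static window.
quat_mean <- function(Q) {
  ref <- Q[1, ]
  sgn <- sign(Q %*% ref)
  sgn[sgn == 0] <- 1
  m <- colMeans(Q * as.numeric(sgn))
  quat_normalize(m)
}

#' Construct a quaternion series
#'
#' @param t numeric time vector, seconds, strictly increasing.
#' @param q n x 4 matrix of unit quaternions (rows).
#' @return object of class `quat_series` with elements `t` and `q`.
#' @export
quat_series <- function(t, q) {
  q <- rbind(q)
  stopifnot(length(t) == nrow(q), ncol(q) == 4L)
  if (any(diff(t) <= 0)) stop("time vector must be strictly increasing")
  nrm <- sqrt(rowSums(q^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("quaternion series rows must be unit norm")
  structure(list(t = t, q = q / nrm), class = "quat_series")
}

#' @export
print.quat_series <- function(x, ...) {
  cat(sprintf("<quat_series> %d samples, %.2f-%.2f s\n",
              length(x$t), min(x$t), max(x$t)))
  invisible(x)
}
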