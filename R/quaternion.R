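# Quaternion utilities. Convention throughout the package: scalar-first
# (w, x, y, z), Hamilton product, right-handed frames. A "pose" quaternion
# maps body-frame vectors into the lab frame: v_lab = q v q*.

#' Normalize quaternions to unit norm
#'
#' @param q numeric length-4 vector or n x 4 matrix (scalar-first).
#' @return same shape, unit-norm rows.
#' @keywords internal
quat_normalize <- function(q) {
  if (is.null(dim(q))) {
    n <- sqrt(sum(q^2))
    if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
    return(q / n)
  }
  n <- sqrt(rowSums(q^2))
  if (any(n < .Machine$double.eps)) stop("cannot normalize a zero quaternion")
  q / n
}

quat_conjugate <- function(q) {
  if (is.null(dim(q))) return(c(q[1], -q[2], -q[3], -q[4]))
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4], deparse.level = 0)
}

#' Hamilton product of quaternions
#'
#' Both arguments may be a single quaternion or an n x 4 matrix; they are
#' recycled row-wise against each other.
#' @keywords internal
quat_multiply <- function(q1, q2) {
  a <- if (is.null(dim(q1))) matrix(q1, 1) else q1
  b <- if (is.null(dim(q2))) matrix(q2, 1) else q2
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  out <- cbind(w, x, y, z, deparse.level = 0)
  if (is.null(dim(q1)) && is.null(dim(q2))) out[1, ] else out
}

#' Rotate 3-vectors by quaternions
#'
#' @param q unit quaternion (length 4) or n x 4 matrix.
#' @param v 3-vector or n x 3 matrix of vectors.
#' @return rotated vectors, n x 3 (or length 3 if both inputs were vectors).
#' @keywords internal
quat_rotate <- function(q, v) {
  qm <- if (is.null(dim(q))) matrix(q, 1) else q
  vm <- if (is.null(dim(v))) matrix(v, 1) else v
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1L && n > 1L) qm <- qm[rep(1L, n), , drop = FALSE]
  if (nrow(vm) == 1L && n > 1L) vm <- vm[rep(1L, n), , drop = FALSE]
  w <- qm[, 1]; u <- qm[, 2:4, drop = FALSE]
  # v' = v + 2 u x (u x v + w v)
  t1 <- cross3(u, vm) + w * vm
  out <- vm + 2 * cross3(u, t1)
  if (is.null(dim(q)) && is.null(dim(v))) out[1, ] else out
}

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1], deparse.level = 0)
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a unit quaternion (body -> lab)
#' @keywords internal
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# yaw (rotation of body x-axis about lab z), for yaw*pitch composed poses
quat_yaw <- function(q) {
  qm <- if (is.null(dim(q))) matrix(q, 1) else q
  ex <- quat_rotate(qm, c(1, 0, 0))
  atan2(ex[, 2], ex[, 1])
}

# pitch above/below horizontal of the body x-axis (positive = x-axis up)
quat_pitch <- function(q) {
  qm <- if (is.null(dim(q))) matrix(q, 1) else q
  ex <- quat_rotate(qm, c(1, 0, 0))
  asin(pmin(1, pmax(-1, ex[, 3])))
}

# compose pose from yaw about lab z and pitch about the (yawed) lateral axis;
# pitch > 0 tilts the forward axis downward (toe-down / plantarflexion)
quat_from_yaw_pitch <- function(yaw, pitch) {
  n <- max(length(yaw), length(pitch))
  yaw <- rep_len(yaw, n); pitch <- rep_len(pitch, n)
  qy <- cbind(cos(yaw / 2), 0, 0, sin(yaw / 2), deparse.level = 0)
  qp <- cbind(cos(pitch / 2), 0, sin(pitch / 2), 0, deparse.level = 0)
  quat_multiply(qy, qp)
}

# minimal rotation taking unit vector a onto unit vector b
quat_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 degrees: any axis orthogonal to a
    ax <- cross3(matrix(a, 1), matrix(c(1, 0, 0), 1))[1, ]
    if (sum(ax^2) < 1e-12) ax <- cross3(matrix(a, 1), matrix(c(0, 1, 0), 1))[1, ]
    return(quat_from_axis_angle(ax, pi))
  }
  ax <- cross3(matrix(a, 1), matrix(b, 1))[1, ]
  quat_normalize(c(1 + d, ax))
}

#' Body-frame angular velocity of a pose sequence
#'
#' Central differences of the quaternion track (one-sided at the edges):
#' omega = 2 * Im(q* dq/dt), expressed in the body frame.
#'
#' @param q n x 4 pose quaternions (body -> lab), uniform sampling.
#' @param rate sampling rate in Hz.
#' @return n x 3 matrix of angular velocity (rad/s, body frame).
#' @keywords internal
quat_angvel <- function(q, rate) {
  n <- nrow(q)
  dq <- q
  if (n >= 3) {
    dq[2:(n - 1), ] <- (q[3:n, ] - q[1:(n - 2), ]) * (rate / 2)
  }
  dq[1, ] <- (q[2, ] - q[1, ]) * rate
  dq[n, ] <- (q[n, ] - q[n - 1, ]) * rate
  om <- quat_multiply(quat_conjugate(q), dq)
  2 * om[, 2:4, drop = FALSE]
}

# integrate body-frame angular velocity forward from q0; omega is n x 3 at
# `rate` Hz. Per step, the rotation increment is the trapezoid of the rate
# plus the second-order coning correction dt^2/12 (w_t x w_{t+1}) -- the
# standard strapdown update, which keeps sub-0.1-degree accuracy through
# the fast foot transients at 100 Hz.
quat_integrate <- function(q0, omega, rate) {
  n <- nrow(omega)
  out <- matrix(0, n, 4)
  out[1, ] <- quat_normalize(q0)
  dt <- 1 / rate
  for (i in seq_len(n - 1L)) {
    w1 <- omega[i, ]; w2 <- omega[i + 1L, ]
    # rotation-vector increment: 4-point interpolatory quadrature of the
    # rate where neighbours exist (accurate through fast foot transients),
    # trapezoid at the segment ends, plus the second-order coning term
    phi <- if (i > 2L && i < n - 2L) {
      dt / 1440 * (11 * omega[i - 2L, ] - 93 * omega[i - 1L, ] +
                   802 * w1 + 802 * w2 - 93 * omega[i + 2L, ] +
                   11 * omega[i + 3L, ])
    } else if (i > 1L && i < n - 1L) {
      dt / 24 * (-omega[i - 1L, ] + 13 * w1 + 13 * w2 - omega[i + 2L, ])
    } else {
      dt / 2 * (w1 + w2)
    }
    phi <- phi + dt^2 / 12 * cross3(matrix(w1, 1), matrix(w2, 1))[1, ]
    ang <- sqrt(sum(phi^2))
    dq <- if (ang < 1e-14) c(1, 0, 0, 0) else
      c(cos(ang / 2), sin(ang / 2) * phi / ang)
    out[i + 1L, ] <- quat_normalize(quat_multiply(out[i, ], dq))
  }
  out
}

#' Sample rotations uniformly over SO(3)
#'
#' Shoemake's subgroup-algorithm construction from three uniform variates.
#' Uses R's RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix of unit quaternions (scalar-first).
#' @export
sample_uniform_quaternion <- function(n = 1L) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  cbind(w = b * cos(2 * pi * u3),
        x = a * sin(2 * pi * u2),
        y = a * cos(2 * pi * u2),
        z = b * sin(2 * pi * u3))
}
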