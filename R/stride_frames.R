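# Per-stride coordinate system: origin at the stride's first sample, x-axis
# along the horizontal start-to-end displacement, z the lab vertical,
# y = z x x (right-handed). The rotation is restricted to be about the
# vertical, so heights are carried over exactly.

#' Express a lab-frame trajectory segment in its stride frame
#'
#' @param traj_segment n x 3 matrix of lab-frame positions (m), n >= 2.
#' @return list with `trajectory` (a `stride_trajectory`: `samples` n x 3 in
#'   the stride frame) and `frame` (a `stride_frame`: `origin` 3-vector and
#'   `rotation` unit quaternion, lab -> stride, plus the stride `heading` in
#'   radians).
#' @export
to_stride_frame <- function(traj_segment) {
  x <- as.matrix(traj_segment)
  if (nrow(x) < 2L) stop("a stride segment needs at least 2 samples")
  origin <- x[1, ]
  d <- x[nrow(x), ] - origin
  if (sqrt(sum(d[1:2]^2)) < 1e-6)
    stop("horizontal start-to-end displacement below 1e-6 m: ",
         "stride direction undefined")
  heading <- atan2(d[2], d[1])
  # lab -> stride: rotate by -heading about the vertical
  q <- quat_from_axis_angle(c(0, 0, 1), -heading)
  samples <- quat_rotate(q, sweep(x, 2, origin))
  frame <- structure(list(origin = origin, rotation = q, heading = heading),
                     class = "stride_frame")
  traj <- structure(list(samples = samples), class = "stride_trajectory")
  list(trajectory = traj, frame = frame)
}

#' Map a stride-frame trajectory back to the lab frame
#'
#' Exact inverse of [to_stride_frame()].
#'
#' @param traj a `stride_trajectory` (or bare n x 3 matrix).
#' @param frame a `stride_frame`.
#' @return n x 3 lab-frame trajectory.
#' @export
invert_stride_frame <- function(traj, frame) {
  s <- if (is.list(traj)) traj$samples else as.matrix(traj)
  sweep(quat_rotate(quat_conjugate(frame$rotation), s), 2, frame$origin, `+`)
}

#' Turning angle between two consecutive stride frames
#'
#' Unsigned angle, in degrees, between the horizontal x-axes (main movement
#' directions) of two strides of the same foot.
#'
#' @param prev_frame,cur_frame `stride_frame`s from consecutive strides.
#' @return angle in [0, 180] degrees.
#' @export
turning_angle <- function(prev_frame, cur_frame) {
  d <- abs(cur_frame$heading - prev_frame$heading) %% (2 * pi)
  if (d > pi) d <- 2 * pi - d
  d * 180 / pi
}

#' Classify a stride as turning
#'
#' @param angle turning angle in degrees.
#' @param threshold classification threshold, degrees.
#' @return logical.
#' @export
classify_turn <- function(angle, threshold = 20) angle > threshold

#' Calibrate the horizontal plane of movement
#'
#' Estimates the floor normal from the centroid positions of the foot during
#' steady (foot-flat) periods via principal component analysis: the
#' least-variance principal direction of the support points is the plane
#' normal. Returns the rotation that maps it onto lab +z.
#'
#' @param positions n x 3 matrix of steady-period support positions (e.g.,
#'   steady-interval centroids of the heel/toe centroid trajectory).
#' @return list with `rotation` (unit quaternion to apply to all lab-frame
#'   trajectories) and `normal` (the estimated plane normal, positive z).
#' @export
calibrate_horizontal_plane <- function(positions) {
  x <- as.matrix(positions)
  if (nrow(x) < 3L) stop("need at least 3 steady support points")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-30))
    stop("support points are collinear; plane normal undefined")
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal
  list(rotation = quat_between(normal, c(0, 0, 1)), normal = normal)
}
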