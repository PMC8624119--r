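# Conventional strapdown gait analysis: orientation from gyroscope
# integration (re-initialized from gravity at each foot-flat), gravity
# removal, zero-velocity double integration with linear dedrifting, and a
# rigid-shoe trigonometric toe-clearance model.

#' Shoe geometry for the rigid-shoe toe clearance model
#'
#' @param sensor_to_toe_distance straight-line distance from the sensor to
#'   the shoe tip, m.
#' @param sensor_pitch_offset fixed pitch offset, rad; `NA` requests
#'   auto-calibration during the preceding foot-flat interval.
#' @export
shoe_geometry <- function(sensor_to_toe_distance = 0.105,
                          sensor_pitch_offset = NA) {
  if (sensor_to_toe_distance <= 0) stop("sensor-to-toe distance must be > 0")
  structure(list(sensor_to_toe_distance = sensor_to_toe_distance,
                 sensor_pitch_offset = sensor_pitch_offset),
            class = "shoe_geometry")
}

#' Sensor orientation from gyroscope integration
#'
#' Initial inclination (roll/pitch) comes from the direction of the mean
#' accelerometer vector over each steady interval (yaw is unobservable from
#' gravity and set to 0); angular rate is then integrated forward, and the
#' estimate is re-initialized at every steady-interval midpoint. Samples
#' before the first steady interval are covered by backward integration.
#'
#' @param imu an `imu_sequence`.
#' @param steady steady intervals (half-open, 0-based), e.g. from
#'   [detect_steady_imu()].
#' @return n x 4 matrix of unit quaternions (sensor -> lab).
#' @export
estimate_orientation <- function(imu, steady) {
  n <- nrow(imu$gyro)
  if (nrow(steady) < 1L) stop("need at least one steady interval")
  steady <- steady[order(steady[, 1]), , drop = FALSE]
  mids <- mid_stance_events(steady)
  q_init <- t(vapply(seq_len(nrow(steady)), function(k) {
    # average over the central half of the interval: the detector's energy
    # window lets a few end-of-landing samples leak into the interval edges,
    # and their deceleration transient would tilt the gravity estimate
    len <- steady[k, 2] - steady[k, 1]
    lo <- steady[k, 1] + max(0L, floor(len / 4))
    hi <- steady[k, 2] - max(0L, floor(len / 4))
    f <- colMeans(imu$accel[(lo + 1L):hi, , drop = FALSE])
    mag <- sqrt(sum(f^2))
    if (abs(mag - GRAVITY) > 0.2 * GRAVITY)
      warning(sprintf(
        "steady accelerometer magnitude %.2f deviates >20%% from g; ",
        mag), "inclination may be unreliable")
    quat_between(f / mag, c(0, 0, 1))
  }, numeric(4)))
  out <- matrix(NA_real_, n, 4)
  # backward from the first steady midpoint
  first <- mids[1] + 1L
  if (first > 1L) {
    idx <- first:1
    back <- quat_integrate(q_init[1, ], -imu$gyro[idx, , drop = FALSE],
                           imu$rate)
    out[idx, ] <- back
  }
  for (k in seq_along(mids)) {
    from <- mids[k] + 1L
    to <- if (k < length(mids)) mids[k + 1L] + 1L else n
    idx <- from:to
    seg <- quat_integrate(q_init[k, ], imu$gyro[idx, , drop = FALSE],
                          imu$rate)
    if (k < length(mids)) {
      # distribute the accumulated drift linearly over the segment so the
      # estimate re-joins the next steady interval's gravity-derived
      # inclination (orientation analogue of the linear dedrifting step)
      e <- quat_multiply(quat_conjugate(seg[nrow(seg), ]), q_init[k + 1L, ])
      if (e[1] < 0) e <- -e
      ang <- 2 * acos(min(1, e[1]))
      if (ang > 1e-12) {
        ax <- e[2:4] / sqrt(sum(e[2:4]^2))
        w <- seq(0, 1, length.out = nrow(seg))
        corr <- cbind(cos(w * ang / 2), outer(sin(w * ang / 2), ax))
        seg <- quat_multiply(seg, corr)
      }
    }
    out[idx, ] <- seg
  }
  out
}

#' Gravity-free linear acceleration in the lab frame
#'
#' Rotates the specific force into the lab frame and removes gravity, so a
#' stationary sensor yields zero.
#'
#' @param imu an `imu_sequence`.
#' @param orientation n x 4 quaternions (sensor -> lab).
#' @return n x 3 lab-frame linear acceleration, m/s^2.
#' @export
linear_acceleration <- function(imu, orientation) {
  quat_rotate(orientation, imu$accel) +
    matrix(GRAVITY_VEC, nrow(imu$accel), 3, byrow = TRUE)
}

cumtrapz_series <- function(x, dt) {
  n <- nrow(x)
  apply(x, 2, function(v) c(0, cumsum((v[-n] + v[-1]) / 2)) * dt)
}

#' Zero-velocity double integration with linear dedrifting
#'
#' Trapezoidal integration of lab-frame linear acceleration over one stride
#' window bounded by zero-velocity instants: velocity starts at zero, the
#' linear ramp that makes the final velocity zero is subtracted (this
#' cancels a constant acceleration bias exactly), and velocity is
#' integrated to position.
#'
#' @param lin_acc n x 3 lab-frame linear acceleration of one stride window
#'   (mid-stance to mid-stance).
#' @param rate sampling rate, Hz.
#' @return n x 3 lab-frame positions relative to the window start.
#' @export
double_integrate_dedrift <- function(lin_acc, rate) {
  n <- nrow(lin_acc)
  if (n < 2L) stop("stride window too short to integrate")
  dt <- 1 / rate
  v <- cumtrapz_series(lin_acc, dt)
  ramp <- (seq_len(n) - 1) / (n - 1)
  v_dd <- v - outer(ramp, v[n, ])
  cumtrapz_series(v_dd, dt)
}

#' Rigid-shoe toe clearance
#'
#' Standard rigid-lever model: the toe height is the sensor height minus
#' `distance * sin(pitch + offset)`, with the pitch (toe-down positive)
#' taken from the estimated orientation. With `sensor_pitch_offset = NA`
#' the offset and the sensor reference height are calibrated on a foot-flat
#' interval so the clearance is zero there.
#'
#' @param sensor_z vertical sensor positions (m; any fixed reference).
#' @param orientation n x 4 quaternions (sensor -> lab).
#' @param geometry a [shoe_geometry()].
#' @param flat_idx 1-based sample indices of a foot-flat interval used for
#'   calibration.
#' @return toe clearance series (m, zero during the calibration flat).
#' @export
toe_clearance_rigid_shoe <- function(sensor_z, orientation, geometry,
                                     flat_idx) {
  if (is.null(geometry$sensor_to_toe_distance))
    stop("missing shoe geometry")
  pitch_down <- -quat_pitch(orientation)
  off <- geometry$sensor_pitch_offset
  if (is.na(off)) off <- -mean(pitch_down[flat_idx])
  z_ref <- mean(sensor_z[flat_idx])
  d <- geometry$sensor_to_toe_distance
  flat_term <- mean(sin(pitch_down[flat_idx] + off))
  (sensor_z - z_ref) - d * (sin(pitch_down + off) - flat_term)
}

# FC from a vertical-acceleration series: absolute minimum over the
# terminal portion of (FO, next steady start); shared by the
# prediction-side detector and the conventional baseline
detect_fc_from_acc <- function(acc, fo, steady, search_from = 0.6) {
  steady <- steady[order(steady[, 1]), , drop = FALSE]
  n_win <- nrow(steady) - 1L
  fc <- rep(NA_integer_, max(0L, n_win))
  if (n_win >= 1L) for (k in seq_len(n_win)) {
    if (k > length(fo) || is.na(fo[k])) next
    hi <- steady[k + 1L, 1]
    lo <- fo[k] + 1L + as.integer(ceiling(search_from * (hi - fo[k] - 1L)))
    if (hi - lo < 2L) next
    seg <- acc[(lo + 1L):hi]
    if (max(seg) - min(seg) < 1e-8) next
    fc[k] <- lo + which.min(seg) - 1L
  }
  fc
}

#' Conventional gait analysis of an IMU recording
#'
#' Full strapdown pipeline: steady detection, orientation, gravity removal,
#' per-stride zero-velocity double integration with dedrifting, stride-frame
#' expression, FO/FC detection (acceleration magnitude / vertical sensor
#' acceleration) and parameter extraction with the rigid-shoe MTC.
#'
#' @param imu an `imu_sequence`.
#' @param geometry a [shoe_geometry()].
#' @param steady optional precomputed steady intervals.
#' @return list with `params` (per-stride table, same schema as the
#'   deep-learning side, `method = "conventional"`), `trajectories`
#'   (stride-frame sensor trajectory per window), `fo`, `fc`,
#'   `mid_stance`, `orientation`.
#' @export
strapdown_analysis <- function(imu, geometry = shoe_geometry(),
                               steady = NULL) {
  rate <- imu$rate
  if (is.null(steady)) steady <- detect_steady_imu(imu$gyro, rate)
  steady_in <- steady
  orientation <- estimate_orientation(imu, steady_in)
  lin_acc <- linear_acceleration(imu, orientation)
  accel_mag <- sqrt(rowSums(imu$accel^2))
  fo <- detect_fo(accel_mag, steady_in)
  fc <- detect_fc_from_acc(lin_acc[, 3], fo, steady_in)
  mids <- mid_stance_events(steady_in)
  segs <- segment_between_midstance(mids)

  n_win <- nrow(segs$windows)
  trajs <- vector("list", n_win)
  frames <- vector("list", n_win)
  sp <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    w0 <- segs$windows[k, 1]; w1 <- segs$windows[k, 2]
    idx <- (w0 + 1L):(w1 + 1L)
    pos <- double_integrate_dedrift(lin_acc[idx, , drop = FALSE], rate)
    sf <- try(to_stride_frame(pos), silent = TRUE)
    if (inherits(sf, "try-error")) next
    trajs[[k]] <- sf$trajectory
    frames[[k]] <- sf$frame
    flat_rel <- 1:max(2L, steady_in[k, 2] - w0)  # leading flat of the window
    toe_z <- toe_clearance_rigid_shoe(sf$trajectory$samples[, 3],
                                      orientation[idx, , drop = FALSE],
                                      geometry, flat_rel)
    fo_rel <- if (k <= length(fo) && !is.na(fo[k])) fo[k] - w0 else NA
    fc_rel <- if (k <= length(fc) && !is.na(fc[k])) fc[k] - w0 else NA
    s <- spatial_params(sf$trajectory$samples, sf$trajectory$samples,
                        fo_rel, fc_rel)
    s$mtc <- if (is.na(fo_rel) || is.na(fc_rel)) NA_real_ else
      interior_minimum(toe_z, fo_rel, fc_rel) * 100
    sp[[k]] <- s
  }
  tp <- temporal_params(fo, fc, rate)
  params <- assemble_param_table(sp, frames, tp, fc, rate,
                                 method = "conventional")
  list(params = params, trajectories = trajs, frames = frames, fo = fo,
       fc = fc, mid_stance = mids, orientation = orientation,
       steady = steady_in)
}

# combine per-window spatial parameters, temporal parameters and turning
# flags into the common per-stride table
assemble_param_table <- function(spatial_list, frames, temporal, fc, rate,
                                 method = "network") {
  n_win <- length(spatial_list)
  rows <- list()
  for (k in seq_len(n_win)) {
    if (is.null(spatial_list[[k]])) next
    trow <- temporal[temporal$window == k, , drop = FALSE]
    ang <- if (k >= 2L && !is.null(frames[[k]]) && !is.null(frames[[k - 1L]]))
      turning_angle(frames[[k - 1L]]$frame %||% frames[[k - 1L]],
                    frames[[k]]$frame %||% frames[[k]]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      window = k,
      fc = if (k <= length(fc)) fc[k] else NA_integer_,
      stride_duration = if (nrow(trow)) trow$stride_duration else NA_real_,
      swing_duration = if (nrow(trow)) trow$swing_duration else NA_real_,
      stance_duration = if (nrow(trow)) trow$stance_duration else NA_real_,
      cadence = if (nrow(trow)) trow$cadence else NA_real_,
      stride_length = spatial_list[[k]]$stride_length,
      swing_width = spatial_list[[k]]$swing_width,
      mtc = spatial_list[[k]]$mtc,
      speed = if (nrow(trow))
        gait_speed(spatial_list[[k]]$stride_length, trow$stride_duration)
      else NA_real_,
      turning_angle = ang,
      is_turning = !is.na(ang) & ang > 20,
      method = method)
  }
  if (!length(rows)) return(cbind(empty_param_table()[0, ],
                                  data.frame(method = character(0))))
  do.call(rbind, rows)
}
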