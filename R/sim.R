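# Synthetic gait simulator: biomechanically plausible walking trials with
# heel/toe marker trajectories, foot-mounted IMU signals and ground-truth
# events/parameters.
#
# Kinematic model (one stride, mid-stance to mid-stance):
#   foot-flat  [0, s/2] of the cycle        (stationary, stance_fraction s
#   swing      (s/2, s/2 + beta*(1-s))       centred on mid-stance)
#   landing    [s/2 + beta*(1-s), 1 - s/2]   (heel on ground, toe lowering)
#   foot-flat  [1 - s/2, 1)
# FO (foot off) is the flat->swing boundary, FC (foot contact) the
# swing->landing boundary. Heel and toe clearance are prescribed as C^2
# piecewise curves (incomplete-beta blends between knots); the rigid foot
# pose (origin + yaw*pitch quaternion) is solved from the two curves, so
# heel and toe markers are exactly rigid on the foot.

GRAVITY <- 9.81          # m/s^2, lab frame z-up
GRAVITY_VEC <- c(0, 0, -9.81)

#' Configuration of the synthetic gait generator
#'
#' `speed`, `stride_length` and `turning_angle_per_stride` may be scalars or
#' per-stride vectors of length `n_strides`.
#'
#' @param sampling_rate sampling rate, Hz.
#' @param n_strides number of strides in the trial.
#' @param speed walking speed per stride, m/s.
#' @param stride_length stride length per stride, m.
#' @param stance_fraction fraction of the cycle spent foot-flat, centred on
#'   mid-stance.
#' @param mtc_target minimum toe clearance, m (the interior minimum of the
#'   two-lobed toe-height curve equals this exactly).
#' @param max_heel_rise peak heel clearance during swing, m.
#' @param max_toe_rise peak toe clearance (second lobe), m.
#' @param swing_width_amp peak lateral deviation of the swing, m.
#' @param turning_angle_per_stride heading change per stride, degrees.
#' @param mount_rotation unit quaternion (scalar-first), sensor frame with
#'   respect to the foot frame.
#' @param accel_noise_sd,gyro_noise_sd i.i.d. Gaussian sensor noise, per axis.
#' @param accel_bias,gyro_bias constant sensor-frame biases (3-vectors).
#' @param accel_bias_rw,gyro_bias_rw random-walk intensity of the slowly
#'   varying bias component (units per sqrt(s)), the aggregate of bias
#'   instability, residual calibration error under the high dynamics of
#'   gait, and mount micro-motion. Defaults calibrated so the conventional
#'   strapdown pipeline reproduces its published real-data error magnitude
#'   (~1 cm trajectory MAE); constant biases alone are exactly cancelled by
#'   the dedrifting stages and leave it unrealistically accurate.
#' @param heel_offset,toe_offset,sensor_offset marker/sensor positions in the
#'   foot frame, m. Heel and toe offsets must share the same height.
#' @param speed_range admissible speed range, m/s.
#' @param seed integer seed making the trial reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 100, n_strides = 10L,
                       speed = 1.13, stride_length = 1.3,
                       stance_fraction = 0.5, mtc_target = 0.017,
                       max_heel_rise = 0.15, max_toe_rise = 0.10,
                       swing_width_amp = 0.025,
                       turning_angle_per_stride = 0,
                       mount_rotation = c(1, 0, 0, 0),
                       accel_noise_sd = 0.05, gyro_noise_sd = 0.005,
                       accel_bias = c(0, 0, 0), gyro_bias = c(0, 0, 0),
                       accel_bias_rw = 0.15, gyro_bias_rw = 0.015,
                       heel_offset = c(-0.05, 0, 0.02),
                       toe_offset = c(0.15, 0, 0.02),
                       sensor_offset = c(0.05, 0, 0.05),
                       speed_range = c(0.41, 2.01),
                       seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, n_strides = as.integer(n_strides),
              speed = speed, stride_length = stride_length,
              stance_fraction = stance_fraction, mtc_target = mtc_target,
              max_heel_rise = max_heel_rise, max_toe_rise = max_toe_rise,
              swing_width_amp = swing_width_amp,
              turning_angle_per_stride = turning_angle_per_stride,
              mount_rotation = mount_rotation,
              accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
              accel_bias = accel_bias, gyro_bias = gyro_bias,
              accel_bias_rw = accel_bias_rw, gyro_bias_rw = gyro_bias_rw,
              heel_offset = heel_offset, toe_offset = toe_offset,
              sensor_offset = sensor_offset, speed_range = speed_range,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$sampling_rate > 0, cfg$n_strides >= 0)
  if (cfg$stance_fraction <= 0 || cfg$stance_fraction >= 1)
    stop("stance_fraction must lie in (0, 1)")
  if (any(cfg$speed <= 0)) stop("speed must be positive")
  if (any(cfg$speed < cfg$speed_range[1] - 1e-9) ||
      any(cfg$speed > cfg$speed_range[2] + 1e-9))
    stop(sprintf("speed outside the admissible range [%.2f, %.2f] m/s",
                 cfg$speed_range[1], cfg$speed_range[2]))
  if (abs(sqrt(sum(cfg$mount_rotation^2)) - 1) > 1e-8)
    stop("mount_rotation must be a unit quaternion")
  if (abs(cfg$heel_offset[3] - cfg$toe_offset[3]) > 1e-12)
    stop("heel and toe offsets must share the same foot-frame height")
  if (cfg$toe_offset[1] <= cfg$heel_offset[1])
    stop("toe offset must lie forward of the heel offset")
  for (f in c("speed", "stride_length", "turning_angle_per_stride")) {
    len <- length(cfg[[f]])
    if (!len %in% c(1L, max(1L, cfg$n_strides)))
      stop(sprintf("per-stride parameter '%s' has length %d; expected 1 or %d",
                   f, len, cfg$n_strides))
  }
  invisible(cfg)
}

# incomplete-beta blend: monotone C^2 step 0 -> 1 on [0,1]; slope ~ u^a(1-u)^b.
# (a = b = 2 is the minimum-jerk quintic.)
beta_blend <- function(u, a = 2, b = 2) stats::pbeta(u, a + 1, b + 1)

# evaluate a piecewise blend through knots (w, v) with per-segment skew
piecewise_blend <- function(u, w, v, skew = NULL) {
  nseg <- length(w) - 1L
  if (is.null(skew)) skew <- rep(list(c(2, 2)), nseg)
  out <- numeric(length(u))
  out[u <= w[1]] <- v[1]
  out[u >= w[length(w)]] <- v[length(v)]
  for (i in seq_len(nseg)) {
    sel <- u > w[i] & u < w[i + 1L]
    if (!any(sel)) next
    uu <- (u[sel] - w[i]) / (w[i + 1L] - w[i])
    out[sel] <- v[i] + (v[i + 1L] - v[i]) *
      beta_blend(uu, skew[[i]][1], skew[[i]][2])
  }
  out
}

# swing/landing split of the non-flat (motion) phase; FC at w = BETA_FC
BETA_FC <- 0.7

# Analytic clearance curves of the stride (heights above the flat marker
# height), evaluated at motion-phase coordinate w in [0, 1].
stride_clearance_curves <- function(cfg, w) {
  # Landmark sharpness mirrors the impulsive transients of real gait that
  # symmetric splines would smooth away: a brisk toe-off rise (so the first
  # acceleration-magnitude / toe-acceleration maximum falls within ~2
  # samples of FO), a fast final heel descent peaking just before ground
  # contact (the heel-velocity minimum marking FC), and a steep early
  # landing (the dominant downward toe-acceleration extremum just after
  # FC). Shapes validated against the event detectors across the speed
  # range.
  p2 <- cfg$max_toe_rise
  p1 <- 0.45 * cfg$max_toe_rise
  tfc <- 0.70 * cfg$max_toe_rise
  mtc <- cfg$mtc_target
  toe <- ifelse(
    w <= BETA_FC,
    piecewise_blend(w / BETA_FC,
                    c(0, 0.18, 0.5, 0.8, 1),
                    c(0, p1, mtc, p2, tfc),
                    skew = list(c(2, 4), c(2, 2), c(2, 2), c(2, 2))),
    tfc * (1 - beta_blend((w - BETA_FC) / (1 - BETA_FC), 2, 10)))
  hk <- cfg$max_heel_rise * c(0, 1, 0.30, 0)
  heel <- ifelse(
    w <= BETA_FC,
    piecewise_blend(w / BETA_FC,
                    c(0, 0.3, 0.8, 1), hk,
                    skew = list(c(2, 2), c(2, 2), c(10, 2))),
    0)
  list(heel = heel, toe = toe)
}

per_stride <- function(cfg, field, k) {
  x <- cfg[[field]]
  if (length(x) == 1L) x else x[k]
}

#' Foot pose over one stride
#'
#' Builds the rigid foot pose (origin position and orientation quaternion)
#' for stride `stride_index`, starting at heel position (0, 0) and the
#' cumulative heading implied by the preceding strides' turning angles.
#'
#' @param config a [sim_config()].
#' @param stride_index 1-based stride number.
#' @return a `foot_pose_sequence`: list with `time` (s), `position`
#'   (n x 3, foot origin, lab frame), `orientation` (n x 4 quaternions,
#'   foot -> lab), `rate`, and a `stride_info` attribute holding the phase
#'   boundaries in samples.
#' @export
stride_profile <- function(config, stride_index = 1L) {
  validate_sim_config(config)
  k <- stride_index
  v <- per_stride(config, "speed", k)
  len <- per_stride(config, "stride_length", k)
  if (v <= 0) stop("degenerate stride: speed must be positive")
  tau <- len / v
  rate <- config$sampling_rate
  n <- as.integer(round(tau * rate))
  if (n > 256) stop(sprintf(
    "stride too long for the 256-sample window: %.3f s = %d samples", tau, n))
  if (n < 20) stop("stride too short to resolve gait phases")
  s <- config$stance_fraction
  n_f1 <- as.integer(round(s / 2 * n))
  n_m <- as.integer(round((1 - s) * n))
  turn_prev <- if (k > 1L) {
    ta <- config$turning_angle_per_stride
    if (length(ta) == 1L) ta * (k - 1L) else sum(ta[seq_len(k - 1L)])
  } else 0
  psi0 <- turn_prev * pi / 180
  dpsi <- per_stride(config, "turning_angle_per_stride", k) * pi / 180

  idx <- 0:(n - 1)
  w <- pmin(1, pmax(0, (idx - n_f1) / n_m))
  mj <- beta_blend(w, 2, 2)
  psi <- psi0 + dpsi * mj

  # horizontal progression of the heel along the (possibly turning) heading
  if (abs(dpsi) < 1e-12) {
    px <- len * mj * cos(psi0)
    py <- len * mj * sin(psi0)
  } else {
    dmj <- stats::dbeta(w, 3, 3) / n_m      # d(mj)/d(sample)
    px <- cumsum_trapz(len * dmj * cos(psi))
    py <- cumsum_trapz(len * dmj * sin(psi))
  }
  lat <- config$swing_width_amp * 64 * w^3 * (1 - w)^3
  heel_x <- px - lat * sin(psi)
  heel_y <- py + lat * cos(psi)

  cl <- stride_clearance_curves(config, w)
  dx <- config$toe_offset[1] - config$heel_offset[1]
  ratio <- (cl$heel - cl$toe) / dx
  if (any(abs(ratio) > 0.999))
    stop("clearance curves exceed the rigid heel-toe geometry; reduce rises")
  theta <- asin(ratio)                      # pitch, >0 = plantarflexion
  q <- quat_from_yaw_pitch(psi, theta)

  z_flat <- config$heel_offset[3]           # marker height when foot-flat
  heel_pos <- cbind(heel_x, heel_y, z_flat + cl$heel, deparse.level = 0)
  origin <- heel_pos - quat_rotate(q, config$heel_offset)

  fc <- n_f1 + as.integer(round(BETA_FC * n_m))
  out <- list(time = idx / rate, position = origin, orientation = q,
              rate = rate)
  attr(out, "stride_info") <- list(
    n = n, n_flat1 = n_f1, n_motion = n_m, n_flat2 = n - n_f1 - n_m,
    fo = n_f1, fc = fc, heading_start = psi0, heading_end = psi0 + dpsi,
    duration = n / rate)
  class(out) <- "foot_pose_sequence"
  out
}

cumsum_trapz <- function(d) {
  # cumulative trapezoid of a sampled derivative (unit step)
  n <- length(d)
  c(0, cumsum((d[-n] + d[-1]) / 2))
}

#' Marker trajectories from a foot pose sequence
#'
#' Rigid-body model: marker = foot position + R(orientation) offset.
#'
#' @param poses a `foot_pose_sequence`.
#' @param heel_offset,toe_offset marker offsets in the foot frame, m.
#' @return list with `heel` and `toe` n x 3 lab-frame trajectories.
#' @export
markers_from_pose <- function(poses, heel_offset = c(-0.05, 0, 0.02),
                              toe_offset = c(0.15, 0, 0.02)) {
  stopifnot(length(heel_offset) == 3L, length(toe_offset) == 3L)
  list(heel = poses$position + quat_rotate(poses$orientation, heel_offset),
       toe = poses$position + quat_rotate(poses$orientation, toe_offset))
}

# second discrete derivative, central differences with edge replication
deriv2 <- function(x, rate) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  d <- x
  d[2:(n - 1), ] <- (x[3:n, ] - 2 * x[2:(n - 1), ] + x[1:(n - 2), ]) * rate^2
  d[1, ] <- d[2, ]
  d[n, ] <- d[n - 1, ]
  d
}

# first derivative, central differences with one-sided edges
deriv1 <- function(x, rate) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  d <- x
  d[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) * (rate / 2)
  d[1, ] <- (x[2, ] - x[1, ]) * rate
  d[n, ] <- (x[n, ] - x[n - 1, ]) * rate
  d
}

#' Simulate the inertial sensor output of a foot pose sequence
#'
#' Angular rate is the foot's body-frame angular velocity (quaternion
#' differentiation) expressed in the sensor frame; specific force is the
#' sensor-frame expression of (linear acceleration - gravity), with linear
#' acceleration obtained by double differentiation of the sensor-point
#' trajectory. Constant biases and i.i.d. Gaussian noise are then added.
#'
#' @param poses a `foot_pose_sequence` (uniformly sampled).
#' @param mount_rotation unit quaternion, sensor frame w.r.t. foot frame.
#' @param config a [sim_config()] providing noise, bias and sensor geometry.
#' @param seed optional seed for the noise draw.
#' @return an `imu_sequence`: list(time, accel, gyro, rate).
#' @export
imu_from_pose <- function(poses, mount_rotation = c(1, 0, 0, 0),
                          config = sim_config(), seed = NULL) {
  if (abs(sqrt(sum(mount_rotation^2)) - 1) > 1e-8)
    stop("mount_rotation must be a unit quaternion")
  rate <- poses$rate
  n <- nrow(poses$position)
  sensor <- poses$position + quat_rotate(poses$orientation, config$sensor_offset)
  a_lab <- deriv2(sensor, rate)
  q_total <- quat_multiply(poses$orientation, mount_rotation)
  # specific force f = R^T (a - g): stationary sensor reads +g "upward"
  f <- quat_rotate(quat_conjugate(q_total),
                   a_lab - matrix(GRAVITY_VEC, n, 3, byrow = TRUE))
  omega_foot <- quat_angvel(poses$orientation, rate)
  gyro <- quat_rotate(quat_conjugate(mount_rotation), omega_foot)
  with_seed(seed, {
    dt <- 1 / rate
    rw <- function(sd_rw) if (sd_rw > 0)
      apply(matrix(stats::rnorm(3 * n, sd = sd_rw * sqrt(dt)), n, 3), 2,
            cumsum) else matrix(0, n, 3)
    f <- f + matrix(config$accel_bias, n, 3, byrow = TRUE) +
      rw(config$accel_bias_rw) +
      matrix(stats::rnorm(3 * n, sd = config$accel_noise_sd), n, 3)
    gyro <- gyro + matrix(config$gyro_bias, n, 3, byrow = TRUE) +
      rw(config$gyro_bias_rw) +
      matrix(stats::rnorm(3 * n, sd = config$gyro_noise_sd), n, 3)
  })
  structure(list(time = poses$time, accel = f, gyro = gyro, rate = rate),
            class = "imu_sequence")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Simulate a complete walking trial
#'
#' Concatenates `n_strides` strides (with optional per-stride heading
#' change), producing marker and sensor trajectories, the IMU recording and
#' the generator's ground-truth events and parameters. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_trial`: list with `time`, `heel_traj`, `toe_traj`,
#'   `sensor_traj` (lab frame, m), `imu` (an `imu_sequence`),
#'   `truth_events` (`fo`, `fc`, `mid_stance` 0-based sample indices,
#'   `flat_intervals` half-open [start, end)), `truth_params` (one row per
#'   complete FC-to-FC stride), `mount_rotation`, `ground_height`, `config`.
#' @export
simulate_trial <- function(config) {
  validate_sim_config(config)
  rate <- config$sampling_rate
  nst <- config$n_strides
  if (nst == 0L) {
    empty <- matrix(numeric(0), 0, 3)
    return(structure(list(
      time = numeric(0), heel_traj = empty, toe_traj = empty,
      sensor_traj = empty,
      imu = structure(list(time = numeric(0), accel = empty, gyro = empty,
                           rate = rate), class = "imu_sequence"),
      truth_events = list(fo = integer(0), fc = integer(0),
                          mid_stance = integer(0),
                          flat_intervals = matrix(integer(0), 0, 2)),
      truth_params = empty_param_table(),
      mount_rotation = config$mount_rotation,
      ground_height = config$heel_offset[3], config = config),
      class = "synthetic_trial"))
  }

  strides <- lapply(seq_len(nst), function(k) stride_profile(config, k))
  info <- lapply(strides, attr, "stride_info")
  n_k <- vapply(info, `[[`, integer(1), "n")
  off <- c(0L, cumsum(n_k))                 # mid-stance samples, 0-based

  pos <- matrix(0, off[nst + 1L] + 1L, 3)
  ori <- matrix(0, off[nst + 1L] + 1L, 4)
  shift <- c(0, 0, 0)
  for (k in seq_len(nst)) {
    rows <- (off[k] + 1L):(off[k + 1L])
    pos[rows, ] <- strides[[k]]$position +
      matrix(shift, length(rows), 3, byrow = TRUE)
    ori[rows, ] <- strides[[k]]$orientation
    # heel continuity: next stride starts where this one's heel ended (flat)
    mk <- markers_from_pose(strides[[k]], config$heel_offset, config$toe_offset)
    shift <- shift + mk$heel[nrow(mk$heel), ] - mk$heel[1, ]
    shift[3] <- 0
  }
  # trailing mid-stance sample: the final flat pose
  pos[off[nst + 1L] + 1L, ] <- pos[off[nst + 1L], ]
  ori[off[nst + 1L] + 1L, ] <- ori[off[nst + 1L], ]

  poses <- structure(list(time = (0:off[nst + 1L]) / rate, position = pos,
                          orientation = ori, rate = rate),
                     class = "foot_pose_sequence")
  mk <- markers_from_pose(poses, config$heel_offset, config$toe_offset)
  sensor <- pos + quat_rotate(ori, config$sensor_offset)
  imu <- imu_from_pose(poses, config$mount_rotation, config,
                       seed = config$seed)

  fo <- off[seq_len(nst)] + vapply(info, `[[`, integer(1), "fo")
  fc <- off[seq_len(nst)] + vapply(info, `[[`, integer(1), "fc")
  nf1 <- vapply(info, `[[`, integer(1), "n_flat1")
  nf2 <- vapply(info, `[[`, integer(1), "n_flat2")
  flat <- rbind(
    c(0L, nf1[1]),
    if (nst > 1L) cbind(off[2:nst] - nf2[1:(nst - 1L)], off[2:nst] + nf1[2:nst]),
    c(off[nst + 1L] - nf2[nst], off[nst + 1L] + 1L))
  truth_events <- list(fo = fo, fc = fc, mid_stance = off,
                       flat_intervals = flat)

  trial <- structure(list(
    time = poses$time, heel_traj = mk$heel, toe_traj = mk$toe,
    sensor_traj = sensor, imu = imu, truth_events = truth_events,
    truth_params = NULL, mount_rotation = config$mount_rotation,
    ground_height = config$heel_offset[3], config = config),
    class = "synthetic_trial")
  trial$truth_params <- truth_params_from_trial(trial)
  trial
}

# Minimum toe clearance: the interior local minimum of toe height between
# FO and FC (the mid-swing dip between the two clearance maxima). The toe is
# on the ground at FO itself, so the plain minimum over the interval would
# always sit at toe-off; only strict local minima qualify. NA when no
# interior minimum exists. fo/fc are 0-based sample indices; z is the full
# series.
interior_minimum <- function(z, fo, fc) {
  lo <- fo + 2L; hi <- fc                  # 1-based interior candidates
  if (hi - lo < 2L) return(NA_real_)
  i <- lo:hi
  is_min <- z[i] < z[i - 1L] & z[i] <= z[i + 1L]
  if (!any(is_min)) return(NA_real_)
  min(z[i][is_min])
}

empty_param_table <- function() {
  data.frame(stride = integer(0), stride_duration = numeric(0),
             swing_duration = numeric(0), stance_duration = numeric(0),
             cadence = numeric(0), stride_length = numeric(0),
             swing_width = numeric(0), mtc = numeric(0), speed = numeric(0),
             turning_angle = numeric(0), is_turning = logical(0))
}

# Ground-truth parameter table from the generator's own events and sampled
# trajectories. One row per complete FC-to-FC stride (windows 2..n); all
# spatial quantities in cm, durations in s, cadence in steps/min.
truth_params_from_trial <- function(trial) {
  ev <- trial$truth_events
  rate <- trial$imu$rate
  n_win <- length(ev$mid_stance) - 1L
  if (n_win < 2L) return(empty_param_table())
  frames <- lapply(seq_len(n_win), function(k) {
    seg <- trial$heel_traj[(ev$mid_stance[k] + 1L):(ev$mid_stance[k + 1L] + 1L), ]
    to_stride_frame(seg)
  })
  rows <- lapply(2:n_win, function(k) {
    sd_s <- (ev$fc[k] - ev$fc[k - 1L]) / rate
    sw_s <- (ev$fc[k] - ev$fo[k]) / rate
    st_s <- (ev$fo[k] - ev$fc[k - 1L]) / rate
    sl <- max(frames[[k]]$trajectory$samples[, 1]) * 100
    sw <- max(abs(frames[[k]]$trajectory$samples[, 2])) * 100
    toe_z <- trial$toe_traj[, 3] - trial$toe_traj[ev$mid_stance[k] + 1L, 3]
    mtc <- interior_minimum(toe_z, ev$fo[k], ev$fc[k]) * 100
    ang <- turning_angle(frames[[k - 1L]]$frame, frames[[k]]$frame)
    data.frame(stride = k, stride_duration = sd_s, swing_duration = sw_s,
               stance_duration = st_s, cadence = 120 / sd_s,
               stride_length = sl, swing_width = sw, mtc = mtc,
               speed = sl / sd_s, turning_angle = ang,
               is_turning = ang > 20)
  })
  do.call(rbind, rows)
}
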