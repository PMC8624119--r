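ns <- asNamespace("stridenet")

test_that("stride duration is length/speed on the sample grid", {
  p <- stride_profile(quiet_cfg(speed = 1.13, stride_length = 1.3), 1)
  expect_equal(attr(p, "stride_info")$n, 115L)   # 1.3/1.13 s at 100 Hz
  expect_error(stride_profile(quiet_cfg(speed = 0.0001)),
               "outside the admissible range")
  expect_error(sim_config(speed = 0), "positive")
  # a stride longer than the 256-sample window is rejected
  expect_error(stride_profile(quiet_cfg(speed = 0.45, stride_length = 1.5)),
               "256-sample")
})

test_that("toe-height curve has two maxima with interior minimum at the target", {
  cfg <- quiet_cfg(mtc_target = 0.017)
  w <- seq(0.001, 0.699, length.out = 20001)
  cl <- ns$stride_clearance_curves(cfg, w)
  toe <- cl$toe
  ismax <- which(diff(sign(diff(toe))) == -2) + 1
  ismin <- which(diff(sign(diff(toe))) == 2) + 1
  expect_length(ismax, 2L)
  expect_length(ismin, 1L)
  expect_equal(toe[ismin], 0.017, tolerance = 1e-6)
  # heel curve has a single peak
  heel <- cl$heel
  expect_length(which(diff(sign(diff(heel))) == -2), 1L)
})

test_that("markers are rigid on the foot", {
  p <- stride_profile(quiet_cfg(), 1)
  # identity orientation: marker = position + offset
  ps <- stationary_poses(10)
  mk <- markers_from_pose(ps, c(-0.05, 0, 0.02), c(0.15, 0, 0.02))
  expect_equal(mk$heel, ps$position +
               matrix(c(-0.05, 0, 0.02), 10, 3, byrow = TRUE))
  # pure 90-degree z rotation maps an x offset onto y
  ps$orientation <- matrix(rep(ns$quat_from_axis_angle(c(0, 0, 1), pi / 2),
                               each = 10), 10, 4)
  mk <- markers_from_pose(ps, c(1, 0, 0), c(0, 0, 0))
  expect_equal(mk$heel[1, ], c(0, 1, 0), tolerance = 1e-12)
  # random stride: heel-toe distance constant over time
  mk <- markers_from_pose(p)
  d <- sqrt(rowSums((mk$heel - mk$toe)^2))
  expect_lt(max(d) - min(d), 1e-9)
})

test_that("a stationary foot measures gravity and zero angular rate", {
  cfg <- quiet_cfg()
  imu <- imu_from_pose(stationary_poses(60), config = cfg)
  expect_equal(sqrt(rowSums(imu$accel^2)), rep(9.81, 60), tolerance = 1e-9)
  expect_equal(max(abs(imu$gyro)), 0, tolerance = 1e-9)
  expect_error(imu_from_pose(stationary_poses(10), c(1, 1, 0, 0), cfg),
               "unit quaternion")
})

test_that("a constant accelerometer bias shifts the specific force by its sensor-frame image", {
  p <- stride_profile(quiet_cfg(), 1)
  q_mount <- ns$quat_normalize(c(0.9, 0.1, -0.2, 0.3))
  clean <- imu_from_pose(p, q_mount, quiet_cfg())
  b <- c(0.2, -0.1, 0.05)
  biased <- imu_from_pose(p, q_mount, quiet_cfg(accel_bias = b))
  diffs <- biased$accel - clean$accel
  expect_equal(diffs, matrix(b, nrow(diffs), 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("trials are deterministic and compose strides correctly", {
  expect_equal(nrow(simulate_trial(quiet_cfg(n_strides = 0))$heel_traj), 0L)
  t1 <- simulate_trial(sim_config(n_strides = 4, seed = 9))
  t2 <- simulate_trial(sim_config(n_strides = 4, seed = 9))
  expect_identical(t1, t2)
  expect_error(simulate_trial(sim_config(n_strides = 4, speed = c(1, 1.2))),
               "length")
  # 30 degrees per stride for 4 strides: cumulative heading 120 degrees
  tr <- simulate_trial(quiet_cfg(n_strides = 4,
                                 turning_angle_per_stride = 30))
  heel_dir <- diff(tr$heel_traj[, 1:2])
  # foot heading at the trial end: direction of the heel-toe axis
  axis_end <- tr$toe_traj[nrow(tr$toe_traj), 1:2] -
    tr$heel_traj[nrow(tr$heel_traj), 1:2]
  expect_equal(atan2(axis_end[2], axis_end[1]) * 180 / pi, 120,
               tolerance = 1e-9)
  # consecutive stride displacement directions differ by exactly 30 degrees
  expect_equal(tr$truth_params$turning_angle,
               rep(30, nrow(tr$truth_params)), tolerance = 1e-9)
})

test_that("foot-flat intervals are truly still and markers rest on the ground", {
  tr <- noise_free_trial()
  fl <- tr$truth_events$flat_intervals
  for (i in seq_len(nrow(fl))) {
    # skip one sample at each end: the discrete second difference of the
    # sensor trajectory reaches across the phase boundary there
    idx <- (fl[i, 1] + 2):(fl[i, 2] - 1)
    expect_lt(max(abs(tr$imu$gyro[idx, ])), 1e-9)
    expect_equal(sqrt(rowSums(tr$imu$accel[idx, , drop = FALSE]^2)),
                 rep(9.81, length(idx)), tolerance = 1e-6)
    expect_equal(tr$heel_traj[idx, 3], rep(tr$ground_height, length(idx)),
                 tolerance = 1e-9)
    expect_equal(tr$toe_traj[idx, 3], rep(tr$ground_height, length(idx)),
                 tolerance = 1e-9)
  }
  # truth SL equals the horizontal heel displacement between mid-stances
  ms <- tr$truth_events$mid_stance
  for (k in 2:(length(ms) - 1)) {
    d <- tr$heel_traj[ms[k + 1] + 1, 1:2] - tr$heel_traj[ms[k] + 1, 1:2]
    expect_equal(sqrt(sum(d^2)) * 100,
                 tr$truth_params$stride_length[k - 1], tolerance = 1e-7)
  }
})

test_that("trial bundles survive a write/read round trip", {
  tr <- simulate_trial(sim_config(n_strides = 3, seed = 4))
  path <- file.path(tempdir(), "trial_rt")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(back$heel_traj, tr$heel_traj, tolerance = 1e-12)
  expect_equal(back$imu$accel, tr$imu$accel, tolerance = 1e-12)
  expect_equal(back$truth_events$fc, tr$truth_events$fc)
  expect_equal(back$truth_params$stride_length,
               tr$truth_params$stride_length, tolerance = 1e-9)
  unlink(path, recursive = TRUE)
})
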