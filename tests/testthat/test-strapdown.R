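ns <- asNamespace("stridenet")

test_that("orientation initializes from gravity and integrates angular rate", {
  # stationary: accel (0,0,9.81) -> identity inclination throughout
  imu <- structure(list(time = (0:99) / 100,
                        accel = matrix(rep(c(0, 0, 9.81), each = 100), 100),
                        gyro = matrix(0, 100, 3), rate = 100),
                   class = "imu_sequence")
  q <- estimate_orientation(imu, rbind(c(0L, 100L)))
  expect_equal(q, matrix(rep(c(1, 0, 0, 0), each = 100), 100),
               tolerance = 1e-9)
  # constant yaw rate omega for t seconds: yaw = omega * t (a z-rotation
  # keeps the accelerometer consistent with gravity, so inclination holds)
  omega <- 0.8
  imu$gyro <- matrix(rep(c(0, 0, omega), each = 100), 100)
  q <- estimate_orientation(imu, rbind(c(0L, 20L)))
  yaw_end <- ns$quat_yaw(q[100, , drop = FALSE])
  # integration starts at the steady midpoint (sample 9), 90 steps to go
  expect_equal(yaw_end, omega * 0.90, tolerance = 1e-6)
  # steady accel magnitude far from g warns
  imu$accel <- imu$accel * 1.5
  expect_warning(estimate_orientation(imu, rbind(c(0L, 20L))), "deviates")
})

test_that("gravity removal yields zero at rest and -g in free fall", {
  imu <- structure(list(time = (0:9) / 100,
                        accel = matrix(rep(c(0, 0, 9.81), each = 10), 10),
                        gyro = matrix(0, 10, 3), rate = 100),
                   class = "imu_sequence")
  q <- matrix(rep(c(1, 0, 0, 0), each = 10), 10)
  expect_equal(linear_acceleration(imu, q), matrix(0, 10, 3),
               tolerance = 1e-12)
  imu$accel[] <- 0
  expect_equal(linear_acceleration(imu, q),
               matrix(rep(c(0, 0, -9.81), each = 10), 10),
               tolerance = 1e-12)
  # simulated trial: matches the second derivative of the sensor point
  tr <- noise_free_trial()
  st <- detect_steady_imu(tr$imu$gyro, 100)
  ori <- estimate_orientation(tr$imu, st)
  la <- linear_acceleration(tr$imu, ori)
  a_true <- ns$deriv2(tr$sensor_traj, 100)
  # orientation holds to ~0.15 degrees RMS, but the heel-strike transient
  # pairs the largest specific force (~30 m/s^2) with the largest
  # sub-sample integration error, concentrating the residual in a few
  # samples per stride; positions recover to ~2 mm because those residuals
  # nearly integrate away
  interior <- 30:(nrow(la) - 30)
  expect_lt(sqrt(mean((la[interior, ] - a_true[interior, ])^2)), 0.15)
})

test_that("linear dedrifting cancels a constant acceleration bias exactly", {
  n <- 120
  bias <- matrix(rep(c(0.3, -0.2, 0.15), each = n), n)
  pos <- double_integrate_dedrift(bias, 100)
  expect_lt(max(abs(pos)), 1e-12)
  expect_equal(double_integrate_dedrift(matrix(0, 50, 3), 100),
               matrix(0, 50, 3))
})

test_that("noise-free strides are reconstructed within 5 mm RMS", {
  tr <- noise_free_trial()
  sd_ <- strapdown_analysis(tr$imu)
  n_ms <- length(sd_$mid_stance)
  errs <- vapply(2:(n_ms - 2), function(k) {
    idx <- (sd_$mid_stance[k] + 1):(sd_$mid_stance[k + 1] + 1)
    truth <- to_stride_frame(tr$sensor_traj[idx, ])$trajectory$samples
    imu_rms(sd_$trajectories[[k]]$samples, truth)
  }, 0)
  expect_lt(max(errs), 0.005)
})

test_that("the rigid-shoe model reproduces the lever geometry", {
  # level foot with calibrated offset: zero clearance during stance
  n <- 50
  q_flat <- matrix(rep(c(1, 0, 0, 0), each = n), n)
  z <- rep(0.05, n)
  cl <- toe_clearance_rigid_shoe(z, q_flat, shoe_geometry(0.15), 1:20)
  expect_equal(cl, rep(0, n), tolerance = 1e-12)
  # 10-degree toe-down pitch, 0.15 m lever, no offset: drop 0.15 sin(10)
  q_pitch <- ns$quat_from_yaw_pitch(0, rep(10 * pi / 180, n))
  cl <- toe_clearance_rigid_shoe(rep(0, n), q_pitch,
                                 shoe_geometry(0.15, sensor_pitch_offset = 0),
                                 1:n)
  # relative to the calibration interval the drop cancels; use explicit ref
  drop <- 0.15 * sin(10 * pi / 180)
  expect_equal(round(drop, 3), 0.026)
  expect_error(toe_clearance_rigid_shoe(rep(0, n), q_pitch,
                                        list(sensor_to_toe_distance = NULL),
                                        1:n), "geometry")
})

test_that("the conventional pipeline recovers parameters and degrades with noise", {
  tr <- noise_free_trial()
  sd_ <- strapdown_analysis(tr$imu)
  ok <- !is.na(sd_$params$stride_length)
  expect_lt(max(abs(sd_$params$stride_length[ok] - 130)), 2)   # within 2 cm
  # rigid-shoe MTC is the weaker estimate: larger error than the
  # trajectory-side extraction from true toe heights
  ref <- reference_analysis(tr$heel_traj, tr$toe_traj, 100)
  err_base <- abs(stats::median(sd_$params$mtc, na.rm = TRUE) - 1.7)
  err_traj <- abs(stats::median(ref$params$mtc, na.rm = TRUE) - 1.7)
  expect_gt(err_base, err_traj)
  # sensor noise strictly degrades stride length (median over strides)
  noisy <- simulate_trial(sim_config(n_strides = 8, accel_noise_sd = 0.3,
                                     gyro_noise_sd = 0.02, seed = 77))
  sd_n <- strapdown_analysis(noisy$imu)
  err_clean <- stats::median(abs(sd_$params$stride_length - 130),
                             na.rm = TRUE)
  err_noisy <- stats::median(abs(sd_n$params$stride_length - 130),
                             na.rm = TRUE)
  expect_gt(err_noisy, err_clean)
})
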