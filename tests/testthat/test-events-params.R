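ns <- asNamespace("stridenet")

test_that("the low-pass filter is zero-phase", {
  set.seed(20)
  x <- cumsum(rnorm(300))
  a <- rev(lowpass_filter(rev(x), 100))
  b <- lowpass_filter(x, 100)
  # forward-backward filtering is direction-symmetric away from the edge
  # transients of the padding
  expect_equal(a[31:270], b[31:270], tolerance = 1e-9)
})

test_that("reference events match generator truth within 2 samples", {
  for (v in c(0.8, 1.13, 1.6)) {
    tr <- noise_free_trial(n = 6, speed = v, stride_length = 0.5 + 0.7 * v)
    ref <- reference_events(tr$heel_traj, tr$toe_traj, 100)
    fc_err <- vapply(ref$fc, function(x)
      x - tr$truth_events$fc[which.min(abs(tr$truth_events$fc - x))], 0L)
    fo_err <- vapply(ref$fo, function(x)
      x - tr$truth_events$fo[which.min(abs(tr$truth_events$fo - x))], 0L)
    expect_gte(mean(abs(fc_err) <= 2), 0.95)
    expect_gte(mean(abs(fo_err) <= 2), 0.95)
  }
  # constant trajectories: no events (single steady interval, no windows)
  still <- matrix(0.2, 200, 3)
  expect_warning(ev <- reference_events(still, still, 100), "only steady")
  expect_length(ev$fc, 0L)
})

test_that("foot-off detection finds the first peak after each steady", {
  # constructed pulse train: steadies [0,50) and [150,200), peak at 80
  mag <- rep(9.81, 220)
  mag[75:85] <- 9.81 + c(1, 2, 4, 7, 9, 10, 9, 7, 4, 2, 1)
  steady <- rbind(c(0L, 50L), c(150L, 200L))
  expect_equal(detect_fo(mag, steady), 79L)
  # monotone decreasing after the steady: no local maximum
  dec <- c(rep(0, 50), seq(10, 0, length.out = 100), rep(0, 50))
  expect_true(is.na(detect_fo(dec, rbind(c(0L, 50L), c(150L, 200L)))[1]))
  # simulator: median error within 3 samples
  tr <- noise_free_trial()
  st <- detect_steady_imu(tr$imu$gyro, 100)
  fo <- detect_fo(sqrt(rowSums(tr$imu$accel^2)), st)
  err <- vapply(fo[!is.na(fo)], function(x)
    x - tr$truth_events$fo[which.min(abs(tr$truth_events$fo - x))], 0L)
  expect_lte(stats::median(abs(err)), 3)
})

test_that("foot-contact detection finds the downward-acceleration extremum", {
  # Gaussian toe-height bump late in the swing: the downward-curvature
  # extremum sits exactly at the apex (0-based sample 190)
  n <- 300
  z <- 0.05 * exp(-(((0:(n - 1)) - 190) / 12)^2)
  steady <- rbind(c(0L, 60L), c(220L, 280L))
  fc <- detect_fc(z, fo = 100L, steady, 100)
  expect_equal(fc[1], 190L)
  # linear toe height: zero curvature everywhere -> flagged
  lin <- seq(0, 1, length.out = 300)
  expect_true(is.na(detect_fc(lin, 100L, steady, 100)[1]))
  # simulator with ground-truth toe height: median within 2 samples
  tr <- noise_free_trial()
  st <- detect_steady_imu(tr$imu$gyro, 100)
  fo <- detect_fo(sqrt(rowSums(tr$imu$accel^2)), st)
  fc <- detect_fc(tr$toe_traj[, 3], fo, st, 100)
  err <- vapply(fc[!is.na(fc)], function(x)
    x - tr$truth_events$fc[which.min(abs(tr$truth_events$fc - x))], 0L)
  expect_lte(stats::median(abs(err)), 2)
})

test_that("temporal parameters follow the two-steps-per-stride convention", {
  tp <- temporal_params(fo = c(30L, 150L), fc = c(70L, 190L), rate = 100)
  expect_equal(tp$stride_duration, 1.2)
  expect_equal(tp$cadence, 100)
  expect_equal(tp$swing_duration, 0.4)
  expect_equal(tp$stance_duration, 0.8)
  expect_equal(tp$stride_duration, tp$swing_duration + tp$stance_duration)
  # ordering violations drop the stride rather than reordering
  bad <- temporal_params(fo = c(30L, 80L), fc = c(90L, 85L), rate = 100)
  expect_equal(nrow(bad), 0L)
  # noise-free simulator: stride duration exact, swing/stance within 3
  # samples (constant detector landmark offsets cancel FC-to-FC)
  tr <- noise_free_trial()
  ref <- reference_analysis(tr$heel_traj, tr$toe_traj, 100)
  ok <- stats::complete.cases(ref$params[, c("stride_duration")])
  expect_lt(max(abs(ref$params$stride_duration[ok] -
                    tr$truth_params$stride_duration[1])), 0.005)
  expect_lte(max(abs(ref$params$swing_duration[ok] -
                     tr$truth_params$swing_duration[1])), 0.0301)
  expect_lte(max(abs(ref$params$stance_duration[ok] -
                     tr$truth_params$stance_duration[1])), 0.0301)
})

test_that("spatial parameters recover the generator's stride geometry", {
  tr <- noise_free_trial()
  ref <- reference_analysis(tr$heel_traj, tr$toe_traj, 100)
  expect_lt(max(abs(ref$params$stride_length - 130)), 0.1)   # cm
  expect_lt(max(abs(ref$params$swing_width - 2.5)), 0.1)
  mtc <- ref$params$mtc[!is.na(ref$params$mtc)]
  expect_lt(max(abs(mtc - 1.7)), 0.05)
  # planar stride: no lateral deviation
  flat <- simulate_trial(quiet_cfg(n_strides = 4, swing_width_amp = 0))
  refp <- reference_analysis(flat$heel_traj, flat$toe_traj, 100)
  expect_lt(max(refp$params$swing_width), 1e-6)
})

test_that("gait speed is stride length over stride duration", {
  expect_equal(gait_speed(130, 1), 130)
  expect_equal(gait_speed(129.4, 1.15), 112.5217, tolerance = 1e-4)
  expect_equal(gait_speed(87.3, 0.93) * 0.93, 87.3, tolerance = 1e-9)
  expect_error(gait_speed(100, 0), "zero")
})

test_that("stride matching applies the 0.1 s tolerance one-to-one", {
  fc <- c(100L, 215L, 330L)
  m <- match_strides(fc, fc, 100)
  expect_equal(m$detection_rate, 1)
  expect_equal(nrow(m$pairs), 3L)
  m2 <- match_strides(c(100L, 230L, 330L), fc, 100)   # middle off by 0.15 s
  expect_equal(m2$n_undetected, 1L)
  m3 <- match_strides(c(105L, 215L, 330L), fc, 100)   # off by 0.05 s: kept
  expect_equal(nrow(m3$pairs), 3L)
})
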