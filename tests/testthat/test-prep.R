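ns <- asNamespace("stridenet")

test_that("synchronization recovers a constructed shift", {
  tr <- noise_free_trial()
  expect_equal(synchronize(tr$imu, tr$heel_traj, tr$toe_traj), 0L)
  # advance the IMU by 7 samples relative to the markers
  lag <- 7L
  imu_shift <- tr$imu
  n <- nrow(imu_shift$accel)
  imu_shift$accel <- imu_shift$accel[c((lag + 1):n, rep(n, lag)), ]
  imu_shift$gyro <- imu_shift$gyro[c((lag + 1):n, rep(n, lag)), ]
  expect_equal(synchronize(imu_shift, tr$heel_traj, tr$toe_traj), -7L)
  # pure noise: no meaningful unique peak structure is a caller concern;
  # flat series produce a degenerate correlation with a warning
  imu_flat <- tr$imu
  imu_flat$accel[] <- 9.81 / sqrt(3)
  imu_flat$gyro[] <- 0
  flat <- matrix(0.5, n, 3)
  expect_warning(synchronize(imu_flat, flat, flat), "peak")
})

test_that("the angular-rate energy detector finds foot-flat periods", {
  expect_warning(st_all <- detect_steady_imu(matrix(0, 200, 3), 100),
                 "only steady")
  expect_equal(st_all[1, ], c(start = 0L, end = 200L))
  expect_warning(st_none <- detect_steady_imu(matrix(5, 200, 3), 100),
                 "no steady")
  expect_equal(nrow(st_none), 0L)
  tr <- noise_free_trial()
  st <- detect_steady_imu(tr$imu$gyro, 100)
  fl <- tr$truth_events$flat_intervals
  expect_equal(nrow(st), nrow(fl))
  for (i in seq_len(nrow(fl))) {
    inter <- min(st[i, 2], fl[i, 2]) - max(st[i, 1], fl[i, 1])
    union <- max(st[i, 2], fl[i, 2]) - min(st[i, 1], fl[i, 1])
    expect_gte(inter / union, 0.8)
  }
})

test_that("the marker-speed detector finds foot-flat periods", {
  still <- matrix(0.3, 150, 3)
  expect_warning(st_all <- detect_steady_markers(still, still, 100),
                 "only steady")
  expect_equal(st_all[1, ], c(start = 0L, end = 150L))
  moving <- cbind(seq(0, 1.49, by = 0.01), 0, 0)
  expect_warning(st_none <- detect_steady_markers(moving, moving, 100),
                 "no steady")
  expect_equal(nrow(st_none), 0L)
  tr <- noise_free_trial()
  st <- detect_steady_markers(tr$heel_traj, tr$toe_traj, 100)
  fl <- tr$truth_events$flat_intervals
  expect_equal(nrow(st), nrow(fl))
  mids_det <- mid_stance_events(st)
  mids_true <- floor((fl[, 1] + fl[, 2] - 1) / 2)
  expect_lte(max(abs(mids_det - mids_true)), 3)
})

test_that("mid-stance and segmentation follow the half-open conventions", {
  expect_equal(mid_stance_events(rbind(c(10L, 20L))), 14L)
  expect_equal(mid_stance_events(rbind(c(0L, 1L))), 0L)
  expect_equal(mid_stance_events(rbind(c(3L, 8L))), 5L)
  s <- segment_between_midstance(c(10L, 120L, 240L))
  expect_equal(unname(s$windows), rbind(c(10L, 120L), c(120L, 240L)))
  expect_message(s2 <- segment_between_midstance(c(0L, 300L)), "rejected")
  expect_equal(s2$n_rejected, 1L)
  expect_equal(nrow(s2$windows), 0L)
  expect_equal(nrow(segment_between_midstance(c(5L))$windows), 0L)
  # an n-stride noise-free trial yields n-1 complete stride records
  tr <- noise_free_trial()
  ref <- reference_analysis(tr$heel_traj, tr$toe_traj, 100)
  n <- tr$config$n_strides
  complete <- stats::complete.cases(
    ref$params[, c("stride_duration", "stride_length", "mtc")])
  expect_equal(sum(complete), n - 1L)
})

test_that("padding prepends the initial value and is invertible", {
  w <- matrix(rnorm(80 * 6), 80, 6)
  p <- pad_to_length(w)
  expect_equal(dim(p$data), c(256L, 6L))
  expect_equal(p$valid_length, 80L)
  expect_equal(p$data[1:176, ], matrix(w[1, ], 176, 6, byrow = TRUE))
  expect_equal(unpad(p), w)
  full <- matrix(rnorm(256 * 2), 256, 2)
  expect_equal(pad_to_length(full)$data, full)
  const <- matrix(5, 100, 1)
  expect_equal(pad_to_length(const)$data, matrix(5, 256, 1))
  expect_error(pad_to_length(matrix(0, 300, 2)), "longer")
})

test_that("max-abs scaling is fit on training data and inverts exactly", {
  train <- list(matrix(c(-20, 10), 4, 2, byrow = TRUE),
                matrix(c(5, -8), 4, 2, byrow = TRUE))
  sc <- fit_scaler(train)
  expect_equal(unclass(sc), c(20, 10), ignore_attr = TRUE)
  expect_equal(scaler_transform(matrix(c(10, 5), 1), sc),
               matrix(c(0.5, 0.5), 1))
  x <- matrix(rnorm(40), 10, 4)
  sc2 <- fit_scaler(list(x))
  expect_equal(scaler_inverse(scaler_transform(x, sc2), sc2), x,
               tolerance = 1e-12)
  expect_warning(scaler_transform(matrix(c(30, 5), 1), sc), "exceed")
  expect_error(fit_scaler(list(matrix(0, 3, 2))), "zero maximum")
})

test_that("rotation augmentation preserves norms and leaves targets alone", {
  set.seed(12)
  w <- matrix(rnorm(50 * 6), 50, 6)
  copies <- augment_segment(w, k = 5)
  expect_length(copies, 5L)
  for (cp in copies) {
    expect_equal(sqrt(rowSums(cp[, 1:3]^2)), sqrt(rowSums(w[, 1:3]^2)),
                 tolerance = 1e-9)
    expect_equal(sqrt(rowSums(cp[, 4:6]^2)), sqrt(rowSums(w[, 4:6]^2)),
                 tolerance = 1e-9)
  }
  expect_length(augment_segment(w, k = 0), 0L)
  # dataset growth and target invariance through prepare_batches
  tr <- simulate_trial(sim_config(n_strides = 6, seed = 31))
  segs <- trial_segments(tr, "A")
  b <- prepare_batches(segs, fractions = c(train = 1), k_augment = 2)
  expect_length(b$train$imu, 3L * length(segs))
  tgt <- lapply(b$train$segments, `[[`, "target_window")
  expect_equal(tgt[[1]], tgt[[2]])   # rotated copies share the target
})

test_that("subject-wise splitting is exclusive and matches the rounding rule", {
  set.seed(13)
  ids <- paste0("P", 1:26)
  sp <- split_by_subject(ids)
  expect_equal(lengths(sp), c(train = 16L, validation = 5L, test = 5L))
  for (s in 1:50) {
    set.seed(s)
    sp <- split_by_subject(sample(ids, 200, replace = TRUE))
    expect_length(Reduce(intersect, sp), 0L)
    expect_setequal(unlist(sp), ids)
  }
  expect_equal(split_by_subject("solo", c(all = 1))$all, "solo")
  expect_error(split_by_subject(c("a", "b")), "fewer subjects")
})
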