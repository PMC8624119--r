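# End-to-end pipeline stages: synthetic cohort generation, reference-side
# analysis (markers), training-set assembly, prediction-side analysis
# (IMU + network), conventional baseline, stride matching and validation.

#' Simulate a cohort of walking subjects
#'
#' Draws subject-level gait characteristics (comfortable speed, clearance
#' profile, lateral sway, stance fraction) and per-stride speed jitter, and
#' simulates one trial per subject. Stride length follows the walking speed
#' (L = 0.5 + 0.7 v, plus jitter), keeping stride durations near the
#' typical ~1.1 s. A contiguous block of strides performs a 90-degree turn
#' (22.5 degrees per stride) when `turning = TRUE`, mimicking lap-based
#' walking protocols. Sensor noise and per-trial constant biases emulate
#' consumer-grade IMUs.
#'
#' @param n_subjects number of subjects.
#' @param strides_per_subject strides per trial.
#' @param seed cohort seed.
#' @param noise add sensor noise/biases.
#' @param turning include a turning block per trial.
#' @param mount_rotations random sensor mounting orientation per subject.
#' @return list with `trials` (list of `synthetic_trial`) and `subjects`
#'   (id per trial).
#' @export
simulate_cohort <- function(n_subjects = 10L, strides_per_subject = 12L,
                            seed = 1L, noise = TRUE, turning = TRUE,
                            mount_rotations = FALSE) {
  with_seed(seed, {
    trials <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      v_mean <- stats::runif(1, 0.75, 1.55)
      v <- pmin(1.95, pmax(0.5, v_mean + stats::rnorm(strides_per_subject,
                                                      sd = 0.06)))
      len <- pmax(0.6, 0.5 + 0.7 * v + stats::rnorm(strides_per_subject,
                                                    sd = 0.03))
      turn <- rep(0, strides_per_subject)
      if (turning && strides_per_subject >= 8L) {
        start <- sample(3:(strides_per_subject - 5L), 1)
        turn[start:(start + 3L)] <- 22.5
      }
      mount <- if (mount_rotations) sample_uniform_quaternion(1)[1, ]
               else c(1, 0, 0, 0)
      cfg <- sim_config(
        n_strides = strides_per_subject, speed = v, stride_length = len,
        stance_fraction = stats::runif(1, 0.45, 0.55),
        mtc_target = stats::runif(1, 0.012, 0.024),
        max_heel_rise = stats::runif(1, 0.13, 0.17),
        max_toe_rise = stats::runif(1, 0.085, 0.115),
        swing_width_amp = stats::runif(1, 0.015, 0.04),
        turning_angle_per_stride = turn,
        mount_rotation = mount,
        accel_noise_sd = if (noise) 0.05 else 0,
        gyro_noise_sd = if (noise) 0.005 else 0,
        accel_bias = if (noise) stats::rnorm(3, sd = 0.03) else c(0, 0, 0),
        gyro_bias = if (noise) stats::rnorm(3, sd = 0.01) else c(0, 0, 0),
        accel_bias_rw = if (noise) 0.15 else 0,
        gyro_bias_rw = if (noise) 0.015 else 0,
        seed = sample.int(2^31 - 1, 1))
      trials[[s]] <- simulate_trial(cfg)
    }
    list(trials = trials, subjects = paste0("S", seq_len(n_subjects)))
  })
}

#' Reference-side gait analysis from marker trajectories
#'
#' Horizontal-plane calibration, steady-period detection on the heel/toe
#' centroid, mid-stance segmentation, per-marker stride frames, FC/FO from
#' filtered heel velocity / toe acceleration, and the eight parameters.
#'
#' @param heel_traj,toe_traj n x 3 lab-frame marker trajectories (m).
#' @param rate sampling rate, Hz.
#' @param calibrate estimate and apply the horizontal-plane rotation.
#' @return list with `params` (per-stride table), `events`, `windows`,
#'   `heel_frames`, `heel_trajs`, `toe_trajs`, `mid_stance`.
#' @export
reference_analysis <- function(heel_traj, toe_traj, rate,
                               calibrate = TRUE) {
  steady <- detect_steady_markers(heel_traj, toe_traj, rate)
  if (calibrate && nrow(steady) >= 3L) {
    centroid <- (heel_traj + toe_traj) / 2
    support <- t(vapply(seq_len(nrow(steady)), function(k)
      colMeans(centroid[(steady[k, 1] + 1L):steady[k, 2], , drop = FALSE]),
      numeric(3)))
    cal <- try(calibrate_horizontal_plane(support), silent = TRUE)
    if (!inherits(cal, "try-error")) {
      heel_traj <- quat_rotate(cal$rotation, heel_traj)
      toe_traj <- quat_rotate(cal$rotation, toe_traj)
    }
  }
  ev <- reference_events(heel_traj, toe_traj, rate, steady = steady)
  steady_in <- steady
  mids <- mid_stance_events(steady_in)
  segs <- segment_between_midstance(mids)
  n_win <- nrow(segs$windows)
  heel_frames <- vector("list", n_win)
  heel_trajs <- toe_trajs <- vector("list", n_win)
  sp <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    w0 <- segs$windows[k, 1]; w1 <- segs$windows[k, 2]
    idx <- (w0 + 1L):(w1 + 1L)
    hf <- try(to_stride_frame(heel_traj[idx, , drop = FALSE]), silent = TRUE)
    tf <- try(to_stride_frame(toe_traj[idx, , drop = FALSE]), silent = TRUE)
    if (inherits(hf, "try-error") || inherits(tf, "try-error")) next
    heel_frames[[k]] <- hf$frame
    heel_trajs[[k]] <- hf$trajectory$samples
    toe_trajs[[k]] <- tf$trajectory$samples
    fo_rel <- if (k <= length(ev$fo) && !is.na(ev$fo[k])) ev$fo[k] - w0 else NA
    fc_rel <- if (k <= length(ev$fc) && !is.na(ev$fc[k])) ev$fc[k] - w0 else NA
    sp[[k]] <- spatial_params(hf$trajectory$samples, tf$trajectory$samples,
                              fo_rel, fc_rel)
  }
  tp <- temporal_params(ev$fo, ev$fc, rate)
  params <- assemble_param_table(sp, heel_frames, tp, ev$fc, rate,
                                 method = "reference")
  list(params = params, events = ev, windows = segs$windows,
       heel_frames = heel_frames, heel_trajs = heel_trajs,
       toe_trajs = toe_trajs, mid_stance = mids)
}

#' Build padded stride segments from a trial
#'
#' Segments the IMU recording and the reference trajectories over the same
#' mid-stance windows (detected on the markers, as in training-data
#' preparation), expresses heel and toe in their per-stride frames, and
#' pads everything to the fixed 256-sample window.
#'
#' @param trial a `synthetic_trial` (or any list with `imu`, `heel_traj`,
#'   `toe_traj`).
#' @param subject subject id carried on every segment.
#' @return list of stride segments (`imu_window`, `target_window` 256 x 6
#'   physical units, `valid_length`, `subject`, `window`, `is_turning`).
#' @export
trial_segments <- function(trial, subject = "S1") {
  rate <- trial$imu$rate
  ref <- reference_analysis(trial$heel_traj, trial$toe_traj, rate)
  n_win <- nrow(ref$windows)
  segs <- list()
  for (k in seq_len(n_win)) {
    if (is.null(ref$heel_trajs[[k]])) next
    w0 <- ref$windows[k, 1]; w1 <- ref$windows[k, 2]
    if (w1 - w0 > SEQ_LEN) next
    idx <- (w0 + 1L):(w1 + 1L)
    imu_w <- cbind(trial$imu$accel[idx[-length(idx)], , drop = FALSE],
                   trial$imu$gyro[idx[-length(idx)], , drop = FALSE])
    tgt <- cbind(ref$heel_trajs[[k]][-length(idx), , drop = FALSE],
                 ref$toe_trajs[[k]][-length(idx), , drop = FALSE])
    pi_ <- pad_to_length(imu_w)
    pt <- pad_to_length(tgt)
    ang <- ref$params$turning_angle[match(k, ref$params$window)]
    segs[[length(segs) + 1L]] <- list(
      imu_window = pi_$data, target_window = pt$data,
      valid_length = pi_$valid_length, subject = subject, window = k,
      is_turning = !is.na(ang) && ang > 20)
  }
  segs
}

#' Assemble normalized training/validation/test batches
#'
#' Splits by subject, applies rotation augmentation to the training
#' partition (k rotated copies per segment, targets untouched), fits the
#' per-channel max-abs scalers on the training partition only, and
#' normalizes every partition with those training-set parameters.
#'
#' @param segments list of stride segments from [trial_segments()].
#' @param fractions subject-wise split fractions.
#' @param k_augment rotated copies per training segment.
#' @return list with `train`, `val`, `test` (each `imu`, `target`,
#'   `segments`) and `scaler` (`imu`, `target`).
#' @export
prepare_batches <- function(segments, fractions = c(train = 0.6,
                                                    validation = 0.2,
                                                    test = 0.2),
                            k_augment = 5L) {
  subjects <- vapply(segments, `[[`, character(1), "subject")
  split <- split_by_subject(subjects, fractions)
  part_of <- function(ids) segments[subjects %in% ids]
  train_seg <- part_of(split[[1]])
  # rotation augmentation (training partition only)
  aug <- list()
  for (s in train_seg) {
    aug[[length(aug) + 1L]] <- s
    if (k_augment > 0L) for (w in augment_segment(s$imu_window, k_augment)) {
      s2 <- s; s2$imu_window <- w
      aug[[length(aug) + 1L]] <- s2
    }
  }
  sc_imu <- fit_scaler(lapply(aug, `[[`, "imu_window"))
  sc_tgt <- fit_scaler(lapply(aug, `[[`, "target_window"))
  norm_part <- function(part) {
    list(imu = suppressWarnings(lapply(part, function(s)
           scaler_transform(s$imu_window, sc_imu))),
         target = suppressWarnings(lapply(part, function(s)
           scaler_transform(s$target_window, sc_tgt))),
         segments = part)
  }
  grab <- function(i) if (length(split) >= i) part_of(split[[i]]) else list()
  list(train = norm_part(aug),
       val = norm_part(grab(2L)),
       test = norm_part(grab(3L)),
       scaler = list(imu = sc_imu, target = sc_tgt),
       split = split)
}

#' Prediction-side gait analysis of an IMU recording
#'
#' The deployment pipeline: angular-rate steady detection, mid-stance
#' segmentation, padding and normalization with the model's stored
#' training-set scalers, network prediction, inverse scaling, and event /
#' parameter extraction (FO from acceleration magnitude, FC from the
#' predicted vertical toe trajectory derived twice).
#'
#' @param imu an `imu_sequence`.
#' @param model a trained `trajectory_net`.
#' @return list with `params` (per-stride table, `method = "network"`),
#'   `trajectories` (predicted heel/toe per window), `fo`, `fc`,
#'   `mid_stance`, `windows`.
#' @export
analyze_predictions <- function(imu, model) {
  rate <- imu$rate
  steady <- detect_steady_imu(imu$gyro, rate)
  steady_in <- steady
  mids <- mid_stance_events(steady_in)
  segs <- segment_between_midstance(mids)
  n_win <- nrow(segs$windows)
  if (n_win == 0L)
    return(list(params = assemble_param_table(list(), list(),
                temporal_params(integer(0), integer(0), rate), integer(0),
                rate), trajectories = list(), fo = integer(0),
                fc = integer(0), mid_stance = mids,
                windows = segs$windows))
  windows <- lapply(seq_len(n_win), function(k) {
    idx <- (segs$windows[k, 1] + 1L):segs$windows[k, 2]
    pad_to_length(cbind(imu$accel[idx, , drop = FALSE],
                        imu$gyro[idx, , drop = FALSE]))
  })
  seg_list <- lapply(windows, function(w)
    list(imu_window = w$data, valid_length = w$valid_length))
  pred <- predict_trajectories(model, seg_list)

  # composite predicted toe-height series over the segmented region
  toe_z <- rep(NA_real_, nrow(imu$accel))
  for (k in seq_len(n_win)) {
    idx <- (segs$windows[k, 1] + 1L):segs$windows[k, 2]
    toe_z[idx] <- pred[[k]]$toe[, 3]
  }
  toe_z[is.na(toe_z)] <- 0
  accel_mag <- sqrt(rowSums(imu$accel^2))
  fo <- detect_fo(accel_mag, steady_in)
  fc <- detect_fc(toe_z, fo, steady_in, rate)
  sp <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    w0 <- segs$windows[k, 1]
    fo_rel <- if (k <= length(fo) && !is.na(fo[k])) fo[k] - w0 else NA
    fc_rel <- if (k <= length(fc) && !is.na(fc[k])) fc[k] - w0 else NA
    sp[[k]] <- spatial_params(pred[[k]]$heel, pred[[k]]$toe, fo_rel, fc_rel)
  }
  tp <- temporal_params(fo, fc, rate)
  params <- assemble_param_table(sp, vector("list", n_win), tp, fc, rate,
                                 method = "network")
  list(params = params, trajectories = pred, fo = fo, fc = fc,
       mid_stance = mids, windows = segs$windows)
}

#' Match two per-stride tables and report agreement
#'
#' FC-based greedy matching within the tolerance; the matched test-side
#' strides inherit the reference turning flag (the stride-frame heading is
#' not observable from the network's stride-frame predictions).
#'
#' @param test_params,ref_params per-stride tables carrying `fc` columns.
#' @param rate sampling rate, Hz.
#' @param tol matching tolerance, s.
#' @param turning "include" or "exclude" turning strides.
#' @param alpha equivalence significance level.
#' @return list with `report` (an `agreement_report`), `matched`
#'   (paired tables), `n_undetected`, `detection_rate`.
#' @export
validate_params <- function(test_params, ref_params, rate, tol = 0.1,
                            turning = c("include", "exclude"),
                            alpha = 0.05) {
  turning <- match.arg(turning)
  m <- match_strides(test_params$fc, ref_params$fc, rate, tol)
  if (is.null(m$pairs)) stop("no matched strides")
  ti <- test_params[m$pairs[, 1], , drop = FALSE]
  ri <- ref_params[m$pairs[, 2], , drop = FALSE]
  ti$is_turning <- ri$is_turning
  if (turning == "exclude") {
    keep <- !isTRUE_vec(ri$is_turning)
    ti <- ti[keep, , drop = FALSE]
    ri <- ri[keep, , drop = FALSE]
  }
  rep_ <- agreement_report(ti, ri, alpha = alpha)
  attr(rep_, "turning_mode") <- turning
  list(report = rep_, matched = list(test = ti, reference = ri),
       n_undetected = m$n_undetected, detection_rate = m$detection_rate)
}

#' Rigidly re-orient an IMU recording
#'
#' Applies one rotation to every accelerometer and gyroscope sample,
#' emulating a different sensor mounting.
#'
#' @param imu an `imu_sequence`.
#' @param q unit quaternion (scalar-first).
#' @return the rotated `imu_sequence`.
#' @export
rotate_imu <- function(imu, q) {
  w <- rotate_imu_window(cbind(imu$accel, imu$gyro), q)
  imu$accel <- w[, 1:3, drop = FALSE]
  imu$gyro <- w[, 4:6, drop = FALSE]
  imu
}

#' Robustness of the pipeline to sensor re-orientation
#'
#' Applies `n_rotations` uniformly sampled rigid rotations to the raw IMU
#' vectors, reruns the full prediction pipeline for each, pairs strides
#' with the unrotated run by FC matching, and summarizes per-parameter
#' RMSD, correlation and TOST equivalence.
#'
#' @param imu an `imu_sequence` (a walking trial).
#' @param model a trained `trajectory_net`.
#' @param n_rotations number of sampled rotations.
#' @param alpha equivalence significance level.
#' @return data.frame, one row per parameter.
#' @export
rotation_robustness <- function(imu, model, n_rotations = 1L,
                                alpha = 0.05) {
  base <- analyze_predictions(imu, model)
  qs <- sample_uniform_quaternion(n_rotations)
  orig <- NULL; rot <- NULL
  for (r in seq_len(n_rotations)) {
    res <- analyze_predictions(rotate_imu(imu, qs[r, ]), model)
    m <- match_strides(res$params$fc, base$params$fc, imu$rate)
    if (is.null(m$pairs)) next
    orig <- rbind(orig, base$params[m$pairs[, 2], , drop = FALSE])
    rot <- rbind(rot, res$params[m$pairs[, 1], , drop = FALSE])
  }
  if (is.null(orig) || nrow(orig) < 3L)
    stop("no matched strides between original and rotated runs")
  rows <- lapply(GAIT_PARAMETERS, function(p) {
    x <- rot[[p]]; y <- orig[[p]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      return(data.frame(parameter = p, n = length(x), rmsd = NA,
                        corr = NA, corr_type = NA, zone = NA,
                        equiv_p = NA, equivalent = NA))
    co <- correlation(x, y)
    eq <- equivalence_test(x, y, alpha = alpha)
    data.frame(parameter = p, n = length(x), rmsd = rmsd(x, y),
               corr = co$coefficient, corr_type = co$type, zone = eq$zone,
               equiv_p = eq$p_value, equivalent = eq$equivalent)
  })
  do.call(rbind, rows)
}
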