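# Data preparation: synchronization, steady-period detection, mid-stance
# segmentation, padding to the fixed 256-sample window, max-abs
# normalization, rotation augmentation, and subject-wise splitting.

SEQ_LEN <- 256L

#' Synchronize an IMU recording with reference marker trajectories
#'
#' Finds the lag (in samples) maximizing the cross-correlation between the
#' IMU specific-force magnitude and the magnitude of (centroid acceleration
#' minus gravity) derived from the heel/toe marker centroid. Both series are
#' mean-removed before correlation. A positive lag means the marker-derived
#' series must be advanced by `lag` samples to align with the IMU.
#'
#' @param imu an `imu_sequence`.
#' @param heel_traj,toe_traj n x 3 lab-frame marker trajectories at the same
#'   rate.
#' @param max_lag largest lag searched, samples. The default (one second)
#'   is below the stride period, so the periodic secondary peaks of the
#'   gait signal stay out of the search range.
#' @return integer lag in samples.
#' @export
synchronize <- function(imu, heel_traj, toe_traj, max_lag = 100L) {
  a <- sqrt(rowSums(imu$accel^2))
  centroid <- (heel_traj + toe_traj) / 2
  acc <- deriv2(centroid, imu$rate)
  b <- sqrt(rowSums(sweep(acc, 2, GRAVITY_VEC)^2))
  a <- a - mean(a); b <- b - mean(b)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    # correlate a[t] with b[t - l]
    if (l >= 0) {
      n <- min(length(a) - l, length(b))
      if (n < 2) return(-Inf)
      sum(a[(l + 1):(l + n)] * b[1:n]) / n
    } else {
      n <- min(length(a), length(b) + l)
      if (n < 2) return(-Inf)
      sum(a[1:n] * b[(1 - l):(n - l)]) / n
    }
  }, numeric(1))
  peak <- max(cc)
  near <- which(cc >= peak - 1e-9 * max(abs(peak), 1e-12))
  if (length(near) > 1L)
    warning("correlation peak not unique; choosing the earliest lag")
  lags[near[1]]
}

# sliding-window mean via cumulative sums; window centred, edges truncated
sliding_mean <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

runs_to_intervals <- function(steady, min_len) {
  r <- rle(steady)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])   # half-open, 0-based
}

#' Detect steady (foot-flat) periods from angular rate
#'
#' Angular-rate energy detector: the energy of the angular-rate magnitude in
#' a sliding window (0.15 s) is compared against a threshold proportional to
#' its series mean; below-threshold samples form steady intervals.
#'
#' @param gyro n x 3 angular rate (rad/s) or a magnitude vector.
#' @param rate sampling rate, Hz.
#' @param window energy window length, s.
#' @param threshold_factor threshold as a fraction of the mean energy.
#' @param min_duration minimum interval length, s.
#' @return integer matrix of half-open 0-based sample intervals
#'   `[start, end)`, one row each.
#' @export
detect_steady_imu <- function(gyro, rate, window = 0.15,
                              threshold_factor = 0.5, min_duration = 0.05) {
  mag2 <- if (is.null(dim(gyro))) gyro^2 else rowSums(gyro^2)
  half <- max(1L, round(window * rate / 2))
  if (length(mag2) <= 2L * half + 1L) stop("series shorter than the window")
  energy <- sliding_mean(mag2, half)
  thr <- threshold_factor * mean(energy)
  steady <- energy <= thr           # <=: an all-still series is all steady
  iv <- runs_to_intervals(steady, max(1L, round(min_duration * rate)))
  if (nrow(iv) == 0L || (nrow(iv) == 1L && iv[1, 1] == 0L &&
                         iv[1, 2] == length(mag2)))
    warning("steady detector found ", if (nrow(iv) == 0L) "no" else "only",
            " steady samples on this recording")
  iv
}

#' Detect steady periods from marker trajectories
#'
#' Threshold on the speed of the heel/toe centroid.
#'
#' @param heel_traj,toe_traj n x 3 plane-calibrated trajectories (m).
#' @param rate sampling rate, Hz.
#' @param speed_threshold m/s.
#' @param min_duration minimum interval length, s.
#' @return as [detect_steady_imu()].
#' @export
detect_steady_markers <- function(heel_traj, toe_traj, rate,
                                  speed_threshold = 0.05,
                                  min_duration = 0.05) {
  centroid <- (heel_traj + toe_traj) / 2
  speed <- sqrt(rowSums(deriv1(centroid, rate)^2))
  iv <- runs_to_intervals(speed < speed_threshold,
                          max(1L, round(min_duration * rate)))
  if (nrow(iv) == 0L || (nrow(iv) == 1L && iv[1, 1] == 0L &&
                         iv[1, 2] == length(speed)))
    warning("steady detector found ", if (nrow(iv) == 0L) "no" else "only",
            " steady samples on this recording")
  iv
}

#' Mid-stance instants of steady intervals
#'
#' Midpoint sample of each half-open interval, `floor((start + end - 1) / 2)`.
#'
#' @param intervals matrix of half-open `[start, end)` intervals.
#' @return 0-based sample indices.
#' @export
mid_stance_events <- function(intervals) {
  if (nrow(intervals) == 0L) return(integer(0))
  as.integer(floor((intervals[, 1] + intervals[, 2] - 1L) / 2))
}

#' Segment a series between consecutive mid-stance events
#'
#' @param mid_stance 0-based mid-stance sample indices (>= 2 of them).
#' @param max_len windows longer than this are rejected.
#' @return list with `windows` (matrix of half-open `[start, end)` windows)
#'   and `n_rejected`.
#' @export
segment_between_midstance <- function(mid_stance, max_len = SEQ_LEN) {
  ms <- sort(as.integer(mid_stance))
  if (length(ms) < 2L)
    return(list(windows = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("start", "end"))),
                n_rejected = 0L))
  w <- cbind(start = ms[-length(ms)], end = ms[-1])
  too_long <- (w[, 2] - w[, 1]) > max_len
  if (any(too_long))
    message(sum(too_long), " window(s) longer than ", max_len,
            " samples rejected")
  list(windows = w[!too_long, , drop = FALSE], n_rejected = sum(too_long))
}

#' Pad a window to a fixed length with its initial value
#'
#' Padding is prepended, keeping the stride end at a fixed position for the
#' backward recurrence; each channel is padded with its first valid sample.
#'
#' @param window n x c matrix, n <= L.
#' @param L target length.
#' @return list with `data` (L x c) and `valid_length` (= n).
#' @export
pad_to_length <- function(window, L = SEQ_LEN) {
  w <- as.matrix(window)
  n <- nrow(w)
  if (n > L) stop("window longer than the padded length ", L)
  if (n == L) return(list(data = w, valid_length = n))
  pad <- matrix(w[1, ], L - n, ncol(w), byrow = TRUE)
  list(data = rbind(pad, w), valid_length = n)
}

#' Remove the padding of a padded window
#' @param padded output of [pad_to_length()] (or its `data` with
#'   `valid_length`).
#' @param valid_length number of valid trailing samples.
#' @return the original window.
#' @export
unpad <- function(padded, valid_length = NULL) {
  if (is.list(padded)) {
    valid_length <- padded$valid_length
    padded <- padded$data
  }
  padded[(nrow(padded) - valid_length + 1L):nrow(padded), , drop = FALSE]
}

#' Fit per-channel scaling parameters on the training set
#'
#' Each channel is scaled by its maximum absolute value over all training
#' strides, keeping normalized data in [-1, 1].
#'
#' @param x N x L x C array (or list of L x C matrices) of training windows.
#' @return a `scaling_params` object: vector of per-channel maxima.
#' @export
fit_scaler <- function(x) {
  if (is.list(x)) x <- simplify2array(x)        # L x C x N
  if (length(dim(x)) == 3L) {
    maxima <- apply(abs(x), 2, max)
  } else maxima <- apply(abs(x), 2, max)
  if (any(maxima <= 0)) stop("zero maximum on a channel; cannot scale")
  structure(maxima, class = "scaling_params")
}

#' @rdname fit_scaler
#' @param params a `scaling_params`.
#' @export
scaler_transform <- function(x, params) {
  x <- as.matrix(x)
  out <- sweep(x, 2, unclass(params), `/`)
  if (any(abs(out) > 1 + 1e-12))
    warning("values exceed the training-set maxima (normalized magnitude > 1)")
  out
}

#' @rdname fit_scaler
#' @export
scaler_inverse <- function(x, params) sweep(as.matrix(x), 2, unclass(params), `*`)

#' Rotation augmentation of an IMU stride segment
#'
#' Applies `k` independently sampled uniform rotations to the segment's
#' acceleration and angular-rate vectors (the same rotation to every sample
#' of one copy). Target trajectories are stride-frame and gravity-anchored
#' and stay untouched.
#'
#' @param imu_window L x 6 matrix (3 accel + 3 gyro), physical units.
#' @param k number of rotated copies.
#' @return list of k L x 6 rotated copies.
#' @export
augment_segment <- function(imu_window, k = 5L) {
  if (k <= 0L) return(list())
  qs <- sample_uniform_quaternion(k)
  lapply(seq_len(k), function(i) rotate_imu_window(imu_window, qs[i, ]))
}

# rotate the accel/gyro columns of an L x 6 window by one quaternion;
# emulates remounting the sensor: new sensor frame S' with q = S' -> S,
# so measured vectors transform by R(q)^T
rotate_imu_window <- function(imu_window, q) {
  cbind(quat_rotate(quat_conjugate(q), imu_window[, 1:3, drop = FALSE]),
        quat_rotate(quat_conjugate(q), imu_window[, 4:6, drop = FALSE]))
}

#' Subject-wise data split
#'
#' Assigns whole subjects to partitions so no subject appears in more than
#' one. Counts per partition are `floor(fraction * n_subjects)` for every
#' partition after the first, the remainder going to the first (training)
#' partition; subjects are shuffled with R's RNG, so the split is
#' deterministic under `set.seed()`.
#'
#' @param subjects vector of subject ids (one entry per stride, or the
#'   unique ids themselves).
#' @param fractions partition fractions summing to 1.
#' @return named list of subject-id vectors, one per partition.
#' @export
split_by_subject <- function(subjects, fractions = c(train = 0.6,
                                                     validation = 0.2,
                                                     test = 0.2)) {
  ids <- unique(subjects)
  if (length(ids) < length(fractions))
    stop("fewer subjects than partitions")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  ids <- sample(ids)
  counts <- floor(fractions * length(ids))
  counts[1] <- length(ids) - sum(counts[-1])
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  out <- lapply(seq_along(counts), function(i)
    if (counts[i] == 0L) ids[0] else ids[starts[i]:ends[i]])
  names(out) <- names(fractions)
  out
}
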