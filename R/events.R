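# Gait events and spatiotemporal parameters.
#
# Reference side (marker trajectories): FC from the minimum of vertical heel
# velocity, FO from the maximum of vertical toe acceleration, both after
# zero-lag 20 Hz low-pass filtering, localized within the windows between
# steady periods.
#
# Prediction side (IMU + network output): FO = first local maximum of the
# raw acceleration magnitude after a steady interval; FC = absolute minimum
# of the second discrete derivative of the predicted vertical toe
# trajectory between FO and the next steady interval.
#
# Conventions: a stride record is anchored to a mid-stance-to-mid-stance
# window; its stride duration is FC-to-FC (previous window's FC to this
# window's FC), stance = FC -> next FO, swing = FO -> FC, cadence =
# 120 / stride duration (two steps per stride).

#' Zero-lag first-order Butterworth low-pass filter
#'
#' Bidirectional (forward-backward) filtering, 20 Hz default cutoff.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param rate sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz.
#' @return filtered series, same shape.
#' @export
lowpass_filter <- function(x, rate, cutoff = 20) {
  bf <- signal::butter(1, cutoff / (rate / 2), type = "low")
  filt1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.null(dim(x))) filt1(x) else apply(x, 2, filt1)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Reference gait events from marker trajectories
#'
#' @param heel_traj,toe_traj n x 3 plane-calibrated trajectories (m).
#' @param rate sampling rate, Hz.
#' @param steady optional steady intervals (from
#'   [detect_steady_markers()]); computed when missing.
#' @param cutoff low-pass cutoff, Hz.
#' @return list with `fo`, `fc` (0-based sample indices, one per complete
#'   inter-steady window), `mid_stance`, and `n_undetected`.
#' @export
reference_events <- function(heel_traj, toe_traj, rate, steady = NULL,
                             cutoff = 20) {
  heel_z <- lowpass_filter(heel_traj[, 3], rate, cutoff)
  toe_z <- lowpass_filter(toe_traj[, 3], rate, cutoff)
  heel_v <- deriv1(heel_z, rate)[, 1]
  toe_a <- deriv2(toe_z, rate)[, 1]
  if (is.null(steady))
    steady <- detect_steady_markers(heel_traj, toe_traj, rate)

  n_win <- nrow(steady) - 1L
  fo <- fc <- integer(0)
  n_undetected <- 0L
  if (n_win >= 1L) for (k in seq_len(n_win)) {
    lo <- steady[k, 2]; hi <- steady[k + 1L, 1]   # between the steadies
    if (hi - lo < 4L) { n_undetected <- n_undetected + 1L; next }
    idx <- (lo + 1L):hi                            # 1-based view
    # FC: global minimum of vertical heel velocity in the window
    fc_k <- lo + which.min(heel_v[idx]) - 1L
    # FO: maximum vertical toe acceleration before FC
    if (fc_k - lo < 3L) { n_undetected <- n_undetected + 1L; next }
    idx_fo <- (lo + 1L):fc_k
    fo_k <- lo + which.max(toe_a[idx_fo]) - 1L
    if (fo_k >= fc_k) { n_undetected <- n_undetected + 1L; next }
    fo <- c(fo, fo_k); fc <- c(fc, fc_k)
  }
  list(fo = fo, fc = fc, mid_stance = mid_stance_events(steady),
       n_undetected = n_undetected)
}

#' Foot-off detection from acceleration magnitude
#'
#' The first local maximum of the raw specific-force magnitude after each
#' steady interval.
#'
#' @param accel_magnitude |specific force| series (m/s^2).
#' @param steady steady intervals (half-open, 0-based).
#' @return list with `fo` (0-based indices, NA when no maximum is found
#'   before the next steady interval) per inter-steady window.
#' @export
detect_fo <- function(accel_magnitude, steady) {
  steady <- steady[order(steady[, 1]), , drop = FALSE]
  n_win <- nrow(steady) - 1L
  fo <- rep(NA_integer_, max(0L, n_win))
  if (n_win >= 1L) for (k in seq_len(n_win)) {
    lo <- steady[k, 2]; hi <- steady[k + 1L, 1]
    if (hi - lo < 3L) next
    seg <- accel_magnitude[(lo + 1L):hi]
    lm <- local_maxima(seg)
    if (length(lm)) fo[k] <- lo + lm[1] - 1L
  }
  fo
}

#' Foot-contact detection from predicted vertical toe trajectory
#'
#' Vertical acceleration is the second discrete derivative (central
#' differences, edge replication) of the predicted toe height; FC is its
#' absolute minimum between FO and the start of the next steady interval,
#' searched over the terminal portion of that interval: ground contact can
#' only occur late in the swing, and on smoothed predicted trajectories
#' the toe-off and mid-swing deceleration lobes of the clearance curve can
#' otherwise rival the contact dip.
#'
#' @param toe_z predicted vertical toe series (m).
#' @param fo FO indices per window (from [detect_fo()]).
#' @param steady steady intervals.
#' @param rate sampling rate, Hz.
#' @param search_from fraction of the FO-to-steady interval after which
#'   the minimum is searched.
#' @return FC indices (0-based; NA for windows without a detectable
#'   minimum).
#' @export
detect_fc <- function(toe_z, fo, steady, rate, search_from = 0.6) {
  acc <- deriv2(toe_z, rate)[, 1]
  detect_fc_from_acc(acc, fo, steady, search_from)
}

#' Temporal gait parameters from events
#'
#' @param fo,fc per-window event indices (0-based), aligned.
#' @param rate sampling rate, Hz.
#' @return data.frame with one row per complete FC-to-FC stride: stride,
#'   swing and stance duration (s) and cadence (steps/min); `window` gives
#'   the index of the window whose swing closes the stride.
#' @export
temporal_params <- function(fo, fc, rate) {
  n <- min(length(fo), length(fc))
  out <- data.frame(window = integer(0), stride_duration = numeric(0),
                    swing_duration = numeric(0), stance_duration = numeric(0),
                    cadence = numeric(0))
  if (n < 2L) return(out)
  for (k in 2:n) {
    if (is.na(fc[k]) || is.na(fc[k - 1L]) || is.na(fo[k])) next
    if (!(fc[k - 1L] < fo[k] && fo[k] < fc[k])) next   # ordering violated
    sd_s <- (fc[k] - fc[k - 1L]) / rate
    out <- rbind(out, data.frame(
      window = k, stride_duration = sd_s,
      swing_duration = (fc[k] - fo[k]) / rate,
      stance_duration = (fo[k] - fc[k - 1L]) / rate,
      cadence = 120 / sd_s))
  }
  out
}

#' Spatial gait parameters from stride-frame trajectories
#'
#' SL = maximum heel displacement along the stride frame's x-axis (cm);
#' SW = maximum |y| of the heel (cm); MTC = interior minimum of the toe
#' height between FO and FC, relative to the stride-start ground level (cm).
#'
#' @param heel,toe stride-frame trajectories (n x 3, m) of one window.
#' @param fo,fc event indices relative to the window start (0-based), for
#'   the MTC search.
#' @return one-row data.frame (`stride_length`, `swing_width`, `mtc`; cm).
#' @export
spatial_params <- function(heel, toe, fo = NA, fc = NA) {
  sl <- max(heel[, 1]) * 100
  sw <- max(abs(heel[, 2])) * 100
  mtc <- if (is.na(fo) || is.na(fc)) NA_real_ else
    interior_minimum(toe[, 3] - toe[1, 3], fo, fc) * 100
  data.frame(stride_length = sl, swing_width = sw, mtc = mtc)
}

#' Gait speed
#' @param sl stride length, cm.
#' @param stride_duration s.
#' @return speed in cm/s.
#' @export
gait_speed <- function(sl, stride_duration) {
  if (any(stride_duration == 0)) stop("zero stride duration")
  sl / stride_duration
}

#' Match detected strides to reference strides
#'
#' Greedy one-to-one matching on FC times within a tolerance; only matched
#' pairs enter the agreement statistics.
#'
#' @param detected_fc,reference_fc FC sample indices (0-based).
#' @param rate sampling rate, Hz.
#' @param tol matching tolerance, s.
#' @return list with `pairs` (matrix of detected/reference index pairs,
#'   1-based positions), `n_undetected` (reference strides without a
#'   match) and `detection_rate`.
#' @export
match_strides <- function(detected_fc, reference_fc, rate, tol = 0.1) {
  used <- rep(FALSE, length(detected_fc))
  pairs <- NULL
  for (j in seq_along(reference_fc)) {
    d <- abs(detected_fc - reference_fc[j]) / rate
    d[used | is.na(detected_fc)] <- Inf
    if (length(d) && min(d) <= tol) {
      i <- which.min(d)
      used[i] <- TRUE
      pairs <- rbind(pairs, c(detected = i, reference = j))
    }
  }
  n_un <- length(reference_fc) - NROW(pairs)
  list(pairs = pairs, n_undetected = n_un,
       detection_rate = 1 - n_un / max(1L, length(reference_fc)))
}
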