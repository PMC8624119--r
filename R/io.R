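# Trial bundle input/output: a directory of CSV tables (markers, sensor,
# imu, events, params) with a JSON sidecar documenting units and
# conventions (0-based sample indices, half-open intervals, SI units).

#' Write a synthetic trial to a CSV/JSON bundle
#'
#' @param trial a `synthetic_trial`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(
    df, file.path(path, paste0(name, ".csv")), row.names = FALSE)
  xyz <- function(m, pre) stats::setNames(as.data.frame(m),
                                          paste0(pre, c("_x", "_y", "_z")))
  w(cbind(data.frame(time = trial$time), xyz(trial$heel_traj, "heel"),
          xyz(trial$toe_traj, "toe"), xyz(trial$sensor_traj, "sensor")),
    "markers")
  w(cbind(data.frame(time = trial$imu$time), xyz(trial$imu$accel, "accel"),
          xyz(trial$imu$gyro, "gyro")), "imu")
  ev <- trial$truth_events
  w(data.frame(event = c(rep("fo", length(ev$fo)), rep("fc", length(ev$fc)),
                         rep("mid_stance", length(ev$mid_stance))),
               sample = c(ev$fo, ev$fc, ev$mid_stance)), "events")
  w(as.data.frame(ev$flat_intervals), "flat_intervals")
  w(trial$truth_params, "params")
  meta <- list(
    rate_hz = trial$imu$rate,
    ground_height_m = trial$ground_height,
    mount_rotation_wxyz = trial$mount_rotation,
    units = list(position = "m", accel = "m/s^2", gyro = "rad/s",
                 durations = "s", lengths = "cm", cadence = "steps/min"),
    conventions = list(sample_indices = "0-based",
                       intervals = "half-open [start, end)",
                       quaternions = "scalar-first (w,x,y,z), Hamilton"),
    config = trial$config[setdiff(names(trial$config), "mount_rotation")])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial bundle written by [write_trial()]
#' @param path bundle directory.
#' @return a `synthetic_trial`.
#' @export
read_trial <- function(path) {
  r <- function(name) utils::read.csv(file.path(path, paste0(name, ".csv")))
  mk <- r("markers"); im <- r("imu"); ev <- r("events")
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  grab <- function(df, pre) unname(as.matrix(
    df[, paste0(pre, c("_x", "_y", "_z")), drop = FALSE]))
  fi <- as.matrix(r("flat_intervals"))
  dimnames(fi) <- list(NULL, c("start", "end"))
  cfgl <- meta$config
  cfgl$mount_rotation <- as.numeric(meta$mount_rotation_wxyz)
  cfg <- do.call(sim_config, cfgl)
  structure(list(
    time = mk$time, heel_traj = grab(mk, "heel"), toe_traj = grab(mk, "toe"),
    sensor_traj = grab(mk, "sensor"),
    imu = structure(list(time = im$time, accel = grab(im, "accel"),
                         gyro = grab(im, "gyro"), rate = meta$rate_hz),
                    class = "imu_sequence"),
    truth_events = list(fo = ev$sample[ev$event == "fo"],
                        fc = ev$sample[ev$event == "fc"],
                        mid_stance = ev$sample[ev$event == "mid_stance"],
                        flat_intervals = fi),
    truth_params = r("params"),
    mount_rotation = as.numeric(meta$mount_rotation_wxyz),
    ground_height = meta$ground_height_m,
    config = cfg), class = "synthetic_trial")
}

#' Pipeline configuration
#'
#' One declarative document holding every tunable of the pipeline, with
#' defaults reproducing the method's stated settings (100 Hz, 256-sample
#' windows, 5 augmentation rotations, 0.15 s energy window, 0.1 s stride
#' matching tolerance, 20 degree turning threshold, tuned network
#' configuration). Unknown keys are rejected.
#'
#' @param ... overrides for any top-level default.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sampling_rate = 100,
    window_length = 256L,
    augmentations = 5L,
    energy_window_s = 0.15,
    energy_threshold_factor = 0.5,
    marker_speed_threshold = 0.05,
    min_steady_duration_s = 0.05,
    lowpass_cutoff_hz = 20,
    match_tolerance_s = 0.1,
    turning_threshold_deg = 20,
    equivalence_zone_fraction = 0.05,
    alpha = 0.05,
    split_fractions = c(train = 0.6, validation = 0.2, test = 0.2),
    pad_side = "prepend",
    net = unclass(net_config()),
    sim = list(n_subjects = 10L, strides_per_subject = 12L,
               noise = TRUE, turning = TRUE),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (k in names(over)) defaults[[k]] <- over[[k]]
  structure(defaults, class = "pipeline_config")
}
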