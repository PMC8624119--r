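# Shared fixtures. Heavy artifacts (the desk-scale trained model) are built
# lazily and cached for the whole test run.

quiet_cfg <- function(...) sim_config(accel_noise_sd = 0, gyro_noise_sd = 0,
                                      accel_bias_rw = 0, gyro_bias_rw = 0,
                                      ...)

# a small noise-free trial reused across files
noise_free_trial <- local({
  cache <- NULL
  function(n = 8L, ...) {
    if (is.null(cache)) cache <<- simulate_trial(quiet_cfg(n_strides = n))
    if (n == 8L && !length(list(...))) cache else
      simulate_trial(quiet_cfg(n_strides = n, ...))
  }
})

# stationary foot pose sequence (n samples at the flat pose)
stationary_poses <- function(n = 50L, rate = 100) {
  structure(list(time = (0:(n - 1)) / rate,
                 position = matrix(0, n, 3),
                 orientation = matrix(rep(c(1, 0, 0, 0), each = n), n, 4),
                 rate = rate),
            class = "foot_pose_sequence")
}

imu_rms <- function(a, b) sqrt(mean((a - b)^2))

# --- shared experiment cache -------------------------------------------
# The desk-scale experiment (cohort, rotation-augmented training, test
# predictions and the conventional baseline on one shared noisy test set)
# backs both the network-performance and the rotation-robustness checks.
.experiment_cache <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (!is.null(.experiment_cache$exp)) return(.experiment_cache$exp)
  set.seed(20260901)
  cohort <- simulate_cohort(n_subjects = 26L, strides_per_subject = 40L,
                            seed = 20260901, noise = TRUE, turning = TRUE)
  segments <- list()
  for (i in seq_along(cohort$trials))
    segments <- c(segments, trial_segments(cohort$trials[[i]],
                                           cohort$subjects[i]))
  batches <- prepare_batches(segments, k_augment = 5L)
  cfg <- net_config(units_layer1 = 64L, dropout_rate = 0.1,
                    learning_rate = 3e-3, lr_decay = 0.93,
                    batch_size = 32L, max_epochs = 32L, patience = 32L,
                    seed = 20260901)
  model <- train_model(build_model(cfg), batches$train, batches$val,
                       scaler = batches$scaler)
  .experiment_cache$exp <- list(cohort = cohort, batches = batches,
                                model = model)
  .experiment_cache$exp
}

# independent evaluation cohort shared between the instrument-comparison
# and robustness checks; large enough that the network-vs-baseline
# comparison reflects the expectation over subjects rather than split luck
eval_cohort <- function() {
  if (is.null(.experiment_cache$eval))
    .experiment_cache$eval <- simulate_cohort(
      n_subjects = 12L, strides_per_subject = 20L, seed = 20260902,
      noise = TRUE, turning = TRUE)
  .experiment_cache$eval
}
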