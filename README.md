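# stridenet

Stride-by-stride gait analysis from foot-worn inertial sensors.

`stridenet` estimates per-stride 3-D heel and toe trajectories from a
shoe-mounted IMU (3-axis accelerometer + gyroscope, 100 Hz) with a stacked
bidirectional LSTM, extracts the eight standard spatiotemporal gait
parameters from the predictions, and validates them against an
optical-reference analysis with the field's agreement-statistics protocol.
It is aimed at movement-science researchers who want a complete, inspectable
implementation of the learning-based pipeline next to the conventional
strapdown alternative — plus a synthetic gait simulator that makes every
stage testable without laboratory data.

## The model

Each stride is segmented mid-stance to mid-stance and expressed in its own
stride frame: origin at the stride start, x along the horizontal
start-to-end displacement, z vertical, y = z × x. Trajectories become
inter-stride independent, which is what lets a sequence-to-sequence model
predict them stride by stride. The network is

    (N × 256 × 6) IMU  →  BiLSTM(H, sum-merged) → dropout →
                          BiLSTM(6, sum-merged)  →  (N × 256 × 6) heel+toe

trained with Adam on the flattened-window MSE, channels normalized by
training-set maxima, with 5-fold uniform-rotation augmentation of the IMU
inputs for mounting-orientation robustness (targets are stride-frame and
gravity-anchored, so they stay fixed). Foot contact is detected from the
second derivative of the predicted toe height, foot off from the raw
acceleration magnitude; stride duration is FC-to-FC, cadence =
120/stride-duration (two steps per stride), SL/SW from the predicted heel,
MTC from the interior minimum of the predicted toe height between FO and
FC. The forward pass, backpropagation through time and Adam are implemented
in RcppArmadillo — no external deep-learning framework.

The conventional baseline integrates the gyroscope (gravity-anchored
re-initialization at every foot-flat), removes gravity, double-integrates
with zero-velocity linear dedrifting, and estimates MTC with a rigid-shoe
lever model. The agreement module reports accuracy/precision, Bland–Altman
95% limits, RMSE, Shapiro–Wilk-gated Pearson/Spearman correlation, and TOST
equivalence within ±5% of the reference mean.

## A worked example

```r
library(stridenet)

# simulate one subject: 8 strides at 1.13 m/s, 1.30 m stride length,
# noise-free sensors
trial <- simulate_trial(sim_config(n_strides = 8,
                                   accel_noise_sd = 0, gyro_noise_sd = 0,
                                   accel_bias_rw = 0, gyro_bias_rw = 0))

# reference-side analysis from the marker trajectories
ref <- reference_analysis(trial$heel_traj, trial$toe_traj, rate = 100)
ref$params[2, c("stride_duration", "swing_duration", "stance_duration",
                "cadence", "stride_length", "swing_width", "mtc", "speed")]
#>      stride_duration swing_duration stance_duration  cadence stride_length
#> end1            1.15           0.38            0.77 104.3478           130
#>      swing_width      mtc    speed
#> end1         2.5 1.700333 113.0435

# conventional strapdown analysis of the same trial's IMU data
conv <- strapdown_analysis(trial$imu)
round(conv$params$stride_length[2:4], 1)
#> [1] 129.8 129.8 129.8
```

The reference analysis recovers the generator's ground truth (stride
duration 1.15 s, SL 130 cm, SW 2.5 cm, MTC 1.70 cm, speed 113 cm/s)
exactly up to the detectors' documented sub-2-sample event localization;
the strapdown stride length is within a few millimetres on noise-free
signals. `simulate_cohort()` + `trial_segments()` + `prepare_batches()` +
`train_model()` + `analyze_predictions()` run the full learning pipeline;
`run_simulate()` … `run_validate()` are the staged, on-disk equivalents,
also reachable from a shell via `inst/cli/stridenet.R`.

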