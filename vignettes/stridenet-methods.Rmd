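---
title: "Stride-by-stride gait analysis from foot-worn inertial sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride-by-stride gait analysis from foot-worn inertial sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Clinical gait analysis quantifies walking with a handful of spatiotemporal
parameters per stride: stride, swing and stance duration, cadence, stride
length (SL), swing width (SW), minimum toe clearance (MTC) and gait speed.
The laboratory gold standard derives them from optical marker trajectories;
a foot-worn inertial measurement unit (IMU) — a 3-axis accelerometer and
gyroscope on the shoe dorsum — is the portable alternative. `stridenet`
implements a learning-based estimator: a stacked bidirectional LSTM maps a
stride's raw IMU window directly to the 3-D heel and toe trajectories of
that stride, from which the eight parameters are extracted with classical
event detectors. A conventional strapdown pipeline (gyroscope integration,
gravity removal, zero-velocity double integration with linear dedrifting)
is included as the comparison baseline, and an agreement-statistics module
(Bland–Altman limits, normality-gated correlation, TOST equivalence)
implements the validation protocol.

# Stride-frame formulation

Strides are segmented mid-stance to mid-stance, i.e. between midpoints of
the foot-flat periods, when the foot is stationary on the ground. Each
stride's trajectories are re-expressed in a per-stride coordinate system:
origin at the trajectory's first sample, x-axis along the horizontal
start-to-end displacement, z the lab vertical, y = z × x. The rotation is
restricted to be about the vertical, so heights are carried over exactly.
Heel and toe frames are computed independently; no inter-marker geometry
enters the formulation. This makes strides independent of one another — the
price is that the walking path (and hence turning angles) cannot be
reconstructed from predictions, which is why turning strides are flagged
from the reference side and can be excluded from validation summaries.

A stride's IMU window is padded *before* the stride with its initial
sample value to the fixed length of 256 samples (2.56 s at 100 Hz).
Prepending keeps the pad continuous with the stride start and pins the
stride's end — where the backward recurrence starts — to a fixed position;
the padding side is configurable. Windows longer than 256 samples are
rejected and counted.

# The network

Input and output are (strides × 256 × 6) sequences: 3 accelerometer + 3
gyroscope channels in; heel xyz + toe xyz (stride frame, normalized) out.
Two bidirectional LSTM layers, each sum-merged across directions; the
second layer has 6 units per direction and is itself the output head.
A literal consequence: outputs are bounded in (−2, 2) normalized units,
which suffices because every channel is scaled by its training-set maximum
absolute value into [−1, 1]. The loss is the mean squared error over all
1536 elements of the flattened window (we read the normalising constant and
the summation bound as the same element count), and the batch loss is the
mean of per-sequence losses. Training uses Adam with epoch-wise
reshuffling and early stopping (patience 50 epochs on the validation
loss); the checkpoint with the best validation loss is kept. The tuned
full-scale configuration is 160 units, dropout 0.1, learning rate 1e-3,
batch size 100, at most 350 epochs; a hyperband search (reduction factor
3, two iterations, three executions per trial, bounds 32–160 units,
dropout 0–0.30, learning rate 1e-6–1e-2, batch 100–400) is provided at
desk scale via `tune_hyperparameters()`.

Because no deep-learning framework ships with this package's target
environment — and because the model *is* the package's core — the forward
pass, backpropagation through time and Adam are implemented in
RcppArmadillo. Training runs in single precision (the standard for this
model class); the exported gradient entry point runs in double precision
and is verified against central finite differences to ~1e-7 in the test
suite. Per-timestep updates are batched GEMMs over the whole mini-batch,
and the input projection collapses into one GEMM over the flattened
(batch × time) axis. With a fixed seed, initialization (Glorot uniform,
forget-gate bias 1), shuffling and dropout are reproducible;
bit-reproducibility additionally assumes a single-threaded BLAS.

Rotation augmentation draws quaternions uniformly over SO(3) (Shoemake's
construction from three uniform variates) and applies the same rotation to
every accelerometer and gyroscope sample of a copy, five copies per
training segment by default. Targets are untouched: they live in the
stride frame, whose vertical is gravity-anchored and whose heading is
defined by the trajectory itself, so a sensor re-mount does not move them.

# Event detection and parameters

Reference side (markers): trajectories are low-pass filtered with a
zero-lag bidirectional first-order Butterworth at 20 Hz; foot contact (FC)
is the minimum of vertical heel velocity and foot off (FO) the maximum of
vertical toe acceleration (before the window's FC), localized between
steady periods found by thresholding the heel/toe-centroid speed
(0.05 m/s). The floor is calibrated first by PCA on steady-period support
points: the least-variance principal direction is the plane normal, signed
to point up.

Prediction side (IMU): steady periods come from the angular-rate energy
detector (0.15 s sliding window, threshold = 0.5 × mean energy, minimum
duration 0.05 s); FO is the first local maximum of the raw acceleration
magnitude after a steady interval — orientation-invariant by construction —
and FC is the absolute minimum of the second discrete derivative (central
differences, edge replication) of the *predicted* vertical toe trajectory
between FO and the next steady interval, searched over the terminal 40%
of that interval (configurable). The restriction encodes a physical
constraint — ground contact cannot occur in the early swing — and matters
numerically: on smoothed predicted toe heights the toe-off and mid-swing
deceleration lobes of the clearance curve can rival the contact dip
within a few percent, and without the restriction the argmin flips
between otherwise equivalent runs. No additional smoothing is applied to
the predicted height before differentiation; the network output is
already smooth, and an optional Butterworth pre-filter is available.

Conventions worth stating precisely:

* stride duration is FC-to-FC; stance = FC → next FO; swing = FO → FC;
  cadence = 120 / stride duration (two steps per stride — this is what
  makes a 1.15 s stride correspond to ≈104–107 steps/min);
* SL = maximum heel displacement along the stride frame's x-axis, SW =
  maximum |y| of the heel, both in cm;
* MTC is the *interior local* minimum of toe height between FO and FC
  (the mid-swing dip between the two clearance maxima), relative to the
  stride-start ground level. The plain minimum over the interval would
  always sit at toe-off, where the toe is still on the ground;
* mid-stance of a steady interval [start, end) is floor((start+end−1)/2);
  all indices are 0-based and all intervals half-open;
* detected and reference strides are matched greedily one-to-one on FC
  within 0.1 s; only matched pairs enter agreement statistics, unmatched
  reference strides count as "not detected";
* turning strides are those whose main-movement direction changes by more
  than 20° relative to the preceding stride of the same foot. We measure
  the angle between stride-frame x-axes (displacement directions), the
  minimal definition consistent with the protocol; whether the original
  method used foot azimuth instead is not documented.

# The conventional baseline

Orientation is obtained by integrating the gyroscope with re-initialization
at every steady interval: inclination comes from the direction of the mean
accelerometer vector (gravity) over the *central half* of the interval —
the energy detector lets a few end-of-landing samples leak into interval
edges, and their deceleration transient would otherwise tilt the estimate
by several degrees — and yaw, unobservable from gravity, is set to zero
(harmless: the stride frame removes heading). The per-step rotation
increment uses a 4-/6-point interpolatory quadrature of the sampled rate
plus the second-order coning term; at 100 Hz the foot's heel-strike
transient is fast enough that a plain trapezoid loses about two degrees.
Residual endpoint drift is distributed linearly between
re-initializations, the orientation analogue of the dedrifting below.

Linear acceleration = R(q)·f + g with g = (0, 0, −9.81) m/s², so a
stationary sensor yields zero. Per stride window (bounded by zero-velocity
instants), velocity is the trapezoidal integral with v(start) = 0, the
linear ramp making v(end) = 0 is subtracted — this cancels a constant
acceleration bias *exactly*, which is what makes constant sensor biases
survivable — and position is the trapezoidal integral of the result,
expressed in the stride frame. SL and SW come from the sensor trajectory;
MTC uses a rigid-shoe lever: toe height = sensor height −
distance × sin(pitch + offset), with the offset auto-calibrated on the
preceding foot-flat so clearance is zero there (manual override
available). The sensor trajectory reference is the centroid of the two
sensor-mounted markers, which the simulator emits directly.

# The synthetic gait generator

The generator stands in for a 26-subject treadmill-free walking dataset
with optical reference (not deposited), and its defaults are the study
conditions: 100 Hz sampling, self-selected speeds within 0.41–2.01 m/s,
straight strides and 90° turning blocks (22.5°/stride), foot-flat stance
intervals, two-lobed toe-clearance profiles with a mid-swing minimum,
arbitrary sensor mounting, and a three-part sensor error model: i.i.d.
Gaussian noise, constant biases, and a slowly varying (random-walk) bias
component. The last one matters: linear dedrifting cancels a constant
bias *exactly*, so Gaussian-plus-constant-bias sensors leave the
conventional baseline reconstructing strides at ~2 mm — an order of
magnitude better than its published real-data accuracy (~1 cm). The
random-walk intensities (0.15 m/s²·s^-1/2 accelerometer,
0.015 rad/s·s^-1/2 gyroscope) are the aggregate of bias instability,
residual calibration error under the high dynamics of gait and mount
micro-motion, calibrated once so the conventional pipeline's trajectory
error magnitude matches its published value; they are not tuned per
experiment, and setting them to zero restores the idealized model.

One stride runs mid-stance to mid-stance: foot-flat (the
`stance_fraction` = 0.5 of the cycle, centred on mid-stance), swing from
FO (= flat end), landing from FC (heel strike at 70% of the non-flat
phase, toe still dorsiflexed), flat again. Heel and toe *clearance curves*
are prescribed as C² piecewise incomplete-beta blends between knots — the
(a,b) blend is `pbeta(u, a+1, b+1)`, with (2,2) the minimum-jerk quintic —
and the rigid foot pose is *solved* from the two curves: pitch =
asin((heel − toe)/Δx) with Δx the heel-to-toe offset distance, so the two
markers are exactly rigid on the foot by construction. Horizontal
progression follows a minimum-jerk profile along the (possibly smoothly
turning) heading; lateral sway is a symmetric C² bump of amplitude
`swing_width_amp`. The toe curve's interior minimum equals `mtc_target`
exactly (it is a knot with zero slope); the default 1.7 cm matches typical
young-adult values, as do heel rise (15 cm), toe rise (10 cm) and sway
(2.5 cm). Per-subject variation in the cohort generator draws comfortable
speed, stance fraction, clearance profile and sway from plausible ranges,
with per-stride speed jitter and stride length following
L = 0.5 + 0.7·v.

Two design points deserve emphasis:

* **Landmark sharpness is deliberate.** Real gait has impulsive transients
  at toe-off and heel strike; symmetric splines would smooth them away and
  the classical extremum detectors would then be biased by many samples.
  The toe-off rise (first knot at 18% of swing, skew (2,4)), the fast
  final heel descent (skew (10,2)) and the steep early landing (skew
  (2,10)) place each detector's landmark within ~2 samples of the phase
  boundary across the speed range, which is the accuracy the detectors
  reach on real data. A still sharper heel strike would localize FC to one
  sample but makes the angular-rate pulse too fast for any sample-based
  orientation integrator, degrading the strapdown baseline below its
  documented accuracy; the shipped shapes are the calibrated compromise.
  One consequence: detector-derived swing/stance durations carry a
  constant ≈0.03 s offset on noise-free data (FC ~2 samples early, FO ~1
  late), which cancels in FC-to-FC stride durations.
* **What the simulator does not model.** No ground-reaction forces, no
  joint-level kinematics, no soft-tissue artifact, no marker occlusion or
  mislabelling, no double-support asymmetries, and sensor errors are
  i.i.d. Gaussian plus a constant bias (no scale-factor error, no
  temperature drift). Passing tests therefore demonstrate the pipeline's
  internal consistency and its behaviour under controlled degradation —
  not clinical validity on real recordings.

The IMU model is the exact inverse of the sensing assumptions: angular
rate is the body-frame quaternion derivative expressed in the (arbitrary,
unit-norm `mount_rotation`) sensor frame; specific force is the
sensor-frame image of (double-differentiated sensor-point trajectory −
gravity). Double differentiation uses central differences with edge
replication, making the noise-free strapdown round trip a genuine
end-to-end oracle (≤5 mm RMS per interior stride; ~2 mm in practice).

# Statistics

All comparisons are stride-by-stride on matched pairs. Accuracy is the
mean and precision the standard deviation of signed (IMU − reference) and
absolute differences; limits of agreement are mean ± 1.96 sd (the normal
95% convention, not a t-quantile). Correlation is Pearson when the paired
differences pass Shapiro–Wilk at α = 0.05 and Spearman otherwise (the
normality gate is applied to differences — the quantity both downstream
tests examine — with a switch for raw series), classified as very high
(>0.90), high (0.70–0.90) or negligible (<0.30). Equivalence uses two
one-sided tests within ±5% of the *reference-series* mean (the published
zone arithmetic identifies the reference column as the anchor: ±6.47 cm is
5% of a 129.4 cm mean), paired t or Wilcoxon signed-rank by the same gate,
reporting the larger one-sided p. The rotation-robustness experiment
rotates the raw IMU vectors by uniformly sampled quaternions, reruns the
full prediction pipeline, pairs strides with the unrotated run by FC, and
summarizes RMSD, correlation and equivalence per parameter.

# Problem sizes and numerical choices

The bundled experiments run at desk scale, chosen so the whole suite
trains and validates on one CPU: a 26-subject cohort (16/5/5 split by the
floor-remainder rule, matching the published proportions), 40 strides per
subject, ~620 training segments × (1 + 5 rotations) ≈ 3,800 training
sequences, 64 units, batch 32, learning rate 3e-3 decayed by 0.93 per
epoch, 32 epochs (at batch 100 and a fixed 1e-3 rate the same compute is
update-starved — 19 Adam steps per epoch — and both validation loss and
held-out error are clearly worse). The full-scale configuration
(160 units, 350 epochs, tens of thousands of strides) is supported but
not exercised by tests. Tiny-overfit sanity uses 32 strides and
≤300 epochs.

A desk-scale finding worth stating plainly: under these conditions the
trained network does *not* reach the conventional baseline's trajectory
accuracy (≈14–17 mm vs ≈10–17 mm MAE across evaluation cohorts). More
than 95% of the network's error sits in the forward (stride-length)
channel (~37 mm, against ~2 mm vertically and laterally): absolute
forward displacement must be regressed from the signals, and its
precision is data-volume-limited — full-scale validations of this model
class train on tens of thousands of strides — whereas the zero-velocity
double integration gets displacement almost for free from its endpoint
constraints, and this simulator feeds it exactly the error model it
inverts. The corresponding acceptance check asserts the real-data
ordering (network below baseline) and is expected to fail at desk scale;
the rotation-equivalence property, which does not depend on beating the
baseline, holds for all eight parameters. Degenerate
inputs are rejected loudly: zero speed, strides exceeding the 256-sample
window, zero channel maxima, collinear calibration support, zero-mean
equivalence references, stride displacements under 1e-6 m (direction
undefined). Ties in mid-stance midpoints break by floor; correlation of a
constant series is reported "undefined" rather than coerced.

# Known limitations

The network head bounds outputs to (−2, 2) normalized units by design; a
pathological scaler (fit on corrupt data) could clip. Stride-frame
predictions cannot yield turning angles or absolute paths. MTC from
predictions inherits the network's smoothing of the mid-swing dip and is
the weakest parameter, as is typical for wearable estimates of it; the
rigid-shoe baseline MTC is weaker still. The simulator's realism limits
are listed above; in particular, subject-level idiosyncrasies are drawn
from independent uniform ranges, so the cohort lacks the correlated
structure of real populations.
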