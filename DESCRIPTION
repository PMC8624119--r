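Package: stridenet
Title: Stride-by-Stride Gait Analysis from Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-stride three-dimensional heel and toe trajectories
    from foot-mounted inertial measurement unit (IMU) recordings with a
    stacked bidirectional LSTM sequence-to-sequence network, extracts the
    eight standard spatiotemporal gait parameters (stride, swing and stance
    duration, cadence, stride length, swing width, minimum toe clearance,
    gait speed), and compares the result against a conventional strapdown
    zero-velocity double-integration baseline. Includes a biomechanically
    plausible synthetic gait simulator (marker trajectories, IMU signals and
    ground-truth events), per-stride coordinate transforms, gait event
    detectors, and an instrument-agreement statistics suite (Bland-Altman
    limits of agreement, normality-gated correlation, TOST equivalence).
    The recurrent network, its backpropagation-through-time gradients and
    the Adam optimizer are implemented in compiled code via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    pracma,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
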