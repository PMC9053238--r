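Package: bcisim
Title: Closed-Loop Intracortical BCI Decoding and Orthosis Control Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulation of an intracortical brain-computer
    interface driving a powered arm orthosis for a paralyzed hand.
    Generates seeded synthetic sessions (intent traces, inhomogeneous
    Poisson spike trains, high-gamma local field potentials, rectified-RMS
    EMG with post-stroke co-contraction and flexor-synergy structure),
    processes spike-band voltage into binned counts and leaky-integrated
    population rates, extracts periodogram band-power features
    (100-500 Hz, 50-Hz bins, 500-ms updates), fits and runs continuous
    and discrete neural decoders (ridge linear filter with two-stage
    cursor calibration, position-velocity Kalman filter, linear
    discriminant analysis), implements the myoelectric threshold control
    state machines and decoder-output discretization rules of a powered
    elbow-wrist-hand orthosis, simulates grasp-move-release tasks in
    closed loop, and scores clinical outcomes (Action Research Arm Test
    totals, object release times, pooled two-sample t test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
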