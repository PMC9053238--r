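---
title: "Models and design choices in bcisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in bcisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bcisim)
```

bcisim simulates, end to end, a brain–computer interface in which
intracortical array signals drive the hand motor of a powered arm
orthosis worn by a person with chronic post-stroke hand paralysis. This
vignette explains the generative models, the decoding and control
algorithms, the parameters that matter, and the places where the design
was genuinely open and a choice had to be made.

## The simulation problem

Real data from this setting are access-restricted, and the interesting
engineering questions — does the feature extraction separate movement
from rest, does the calibration protocol produce a usable decoder, does
brain control beat myoelectric control when the forearm is spastic —
are questions about pipeline behaviour, not about any one recording. The
package therefore treats the synthetic-data generator as a first-class,
tested module: its defaults *are* the study conditions, and every
downstream claim is evaluated against data generated under them.

## Generative models

**Intent traces.** A session script is a list of cue epochs
(`rest`, `attempt_open`, `attempt_close`, `wrist_ext`, `squeeze`), each
with a duration. The trace is piecewise constant on a 20-ms grid:
`hand_intent` is 0 at rest, 1 for maximal attempted hand action (0.6
for wrist extension, treated as a sub-maximal hand-related action).
Piecewise-constant intent is deliberately idealized: a real participant
shows variable reaction times and fatigue, so a square-wave recovery
test says nothing about cue-onset latency handling.

**Spiking.** Channel `c` fires as an inhomogeneous Poisson process with
rate `max(0, r0 + g_c · intent(t))`, realized by thinning. Where the published record is silent, the
choices are: the intent-to-rate map is linear with rectification (nothing
finer is identifiable from published rasters), tuning gains alternate in
sign across the active channels by default (differential tuning), and
exactly `n_active_channels` (default 87 of 256) have nonzero gain.
Spike-band voltage, when rendered, is white Gaussian noise plus a fixed
~1.2-ms biphasic template (negative phase first) scaled to
`spike_snr × noise_sd`; only threshold-crossing detection needs to work,
so waveform realism beyond that is a non-goal.

**LFP.** High-gamma power is the only LFP property the pipeline
consumes, so the signal is piecewise-stationary white Gaussian noise
whose one-sided PSD level tracks intent:
`PSD(t) = rest + (move − rest) · intent(t)` on modulated channels
(defaults 1.5 and 12 V²/Hz), constant `rest` elsewhere. Because white
noise of variance σ² at rate `fs` has one-sided PSD `2σ²/fs`, the
per-sample SD is `sqrt(PSD · fs/2)`; this makes the generator and the
periodogram feature module two sides of one Parseval identity, which the
tests exploit. No oscillatory phase structure, 1/f background, or line
noise is modeled — so passing tests demonstrate power-trigger logic, not
robustness to artifacts.

**EMG.** Four rectified-RMS envelopes on a 100-ms grid, generated
directly (the orthosis consumes envelopes, so no raw-EMG stage exists).
Wrist-flexor drive follows hand intent plus noise; the wrist extensor is
coupled to the flexor drive with `cocontraction_gain` (default 0.8,
chosen so that the flexor–extensor correlation induced by the coupling
clearly dominates independent noise), and the biceps adds
`synergy_gain` (default 0.6) times the flexor drive — the abnormal
flexor synergy. Envelopes are `baseline + drive`, clamped at zero.

## Feature extraction

The periodogram is the plain rectangular-taper one-sided DFT estimate,
`P(f_k) = |X_k|²/(fs·N)` doubled except at DC/Nyquist, so that
`sum(P)·df = mean(x²)` holds to machine precision. Band features average
the density over eight non-overlapping 50-Hz bins from 100 to 500 Hz; a
frequency on a bin edge belongs to the lower bin (so a 250-Hz tone is a
200–250 Hz feature). Windows are 1 s with 50% overlap, i.e. one value
every 500 ms, and end-aligned: the value at `t` uses `(t−1, t]`, the
causal convention a real-time system must use. One consequence,
documented and tested: streaming two recordings separately is not the
same as streaming their concatenation, because the seam windows only
exist in the latter.

Two band definitions appear in this problem domain (100–500 Hz tied to
the 10 V²/Hz trigger; 100–1000 Hz for filter-building features);
100–500 Hz is the operative default because the trigger threshold is
defined on it, and the band edges are configuration, not code.

Channel ranking ("most neuromodulated") uses the absolute standardized
mean difference of window band power between movement and rest windows.
A window counts as movement or rest only when it lies fully inside an
epoch; mixed windows are excluded from both the ranking statistic and
the trigger hit/false-alarm rates, since their expected power is
genuinely intermediate. Ties rank by ascending channel index.

## Decoders

**Linear filter.** Lagged binned features (default taps 0–4 bins of
200 ms, i.e. 0–800 ms of history — long enough to span neural-kinematic
latency, short enough to keep the design well-conditioned at one minute
of training data) are standardized (parameters stored in the model) and
fit by ridge least squares with an unpenalized intercept. The default
penalty, `1e-3 ×` mean feature variance (after standardization, simply
`1e-3`), is a light regularizer: enough to stabilize near-collinear
channels, small enough that noiseless recovery tests pass at `ridge = 0`
against a normal-equations oracle to 1e-8.

**Two-stage calibration.** Stage 1 fits on a 60-s open-loop block of a
triangle-wave target cursor (5-s half-period, starting at the top).
Stage 2 repeats the minute with the stage-1 prediction displayed; the
synthetic participant optionally reacts to the prediction error through
an error-driven rate component (`feedback_gain`), and the final filter
is refit on the closed-loop block. The displayed prediction is causal:
while bin `t` accrues, the screen shows the value decoded from bin
`t−1`.

**Kalman filter.** The kinematic state is (position, velocity); `A` and
`W` come from least squares on state transitions, `H` and `Q` from
least squares of observations on states; velocity targets are finite
differences of the cursor trajectory. The update is the textbook
recursion; it is verified against the scalar conjugate-Gaussian
posterior to 1e-10, and `Q = Inf` is honoured as "ignore the
observation". Covariances are checked for symmetry and positive
semi-definiteness on entry.

**LDA.** Hand-rolled pooled-covariance discriminant with priors from
training frequencies, because the decision rule and its deterministic
tie-break (first class wins exact ties) are part of the module contract;
the reference implementation in MASS is used as a cross-check in tests,
never as the implementation. A singular pooled covariance raises an
error that names the `shrinkage` escape hatch.

Decision trees, SVM and KNN — listed alongside LDA in this system
family — are not implemented: the linear filter was the operative
decoder, and generic classifiers add no tested value here.

## Control rules and the closed loop

The discretization rules and myoelectric modes are small decision
tables, and three boundary conventions had to be fixed where the
printed rules are ambiguous or inconsistent:

* dual mode: the hold clause is implemented as the complement of the
  open and close clauses (the printed hold condition overlaps them);
* open/close modes: the exact-threshold boundary goes to the default
  posture branch (closed for open mode, open for close mode);
* the two-threshold rule's hold zone is `AT1 ≤ x < AT2` (the printed
  interval reverses the roles of the two thresholds).

All three are asserted exhaustively over randomized inputs, together
with the partition property (exactly one command per input), the
flexor/extensor exchange symmetry of dual mode, and monotonicity in
`AT`.

The orthosis plant is a rate limiter: aperture in [0, 1], default motor
rate 2 aperture/s (full travel in 0.5 s; the true actuator speed is not
published, and the value only scales release times uniformly). Release
times are computed by linear interpolation of the aperture crossing
inside a step, so the oracle-control release time equals the kinematic
value `gap/rate` exactly at any update rate.

Update rates follow each pathway's natural cadence: 10 Hz for
myoelectric envelopes, 5 Hz for the 200-ms-bin BCI filter, 2 Hz for the
500-ms training-less trigger.

**Spasticity coupling.** In myoelectric close-mode the hand opens only
when the flexor envelope falls below threshold. With the coupling
enabled (the default), the envelope relaxes exponentially
(`tau_relax` = 1 s) toward an elevated floor (0.45, just under the
0.5 threshold) instead of dropping freely to 0.05, and envelope noise
(SD 0.05) makes the crossing time variable across trials. This
reproduces the *direction* of the myoelectric-vs-BCI release-time
difference — the motors oppose the abnormal flexor tone — not its
clinical magnitude, which belongs to one human participant and is
carried only as reference data.

## Spike processing details

The RMS threshold is block RMS over the whole calibration segment times
a signed multiplier (default −4.5, negative-going extracellular
convention); whether the original system used block or running RMS is
unstated, and block RMS is the simpler reproducible choice. Detection
logs the first sample of each crossing run, with a 1-ms lockout.
Binning is half-open `[t, t+Δ)` with Δ = 200 ms and conserves counts.
The leaky integrator is the first-order form
`r_t = r_{t−1}·e^{−Δ/τ} + c_t` (τ default 0.5 s, exposed); its
closed-form step response `c/(1−e^{−Δ/τ})` is a test oracle at 1e-9
relative error. Population traces are per-channel max-normalized before
summation, matching the usual display convention.

## Outcome statistics

The ARAT total is the sum of 19 item scores, each validated to {0,1,2,3}
(errors name the offending item). The release-time comparison is a
pooled-variance two-sample two-tailed t test implemented in closed form,
with the p-value checked in tests against the regularized incomplete
beta function and against `stats::t.test`. The choice of the pooled
variant was itself a verification step: on the packaged release-time
table (33 vs 10 trials) the pooled test gives p ≈ 0.041 while the Welch
test gives p ≈ 0.17, so only the pooled variant is consistent with the
reported p = 0.04; both variants remain callable. The serial clinical
scales (Fugl-Meyer 30/36/38, Motricity Index 48/61.5/75.5, Stroke
Impact Scale 232/269, Jebsen-Taylor 146 s vs 95 s) are single-subject
measurements with no published item-level inputs; the report echoes
them as stored reference data and recomputes nothing from them.

## Determinism and seeds

Every stochastic generator takes a mandatory seed and leaves the global
RNG state untouched (seed handling is save/restore-local). Multi-stage
commands expand one master seed into per-stage sub-seeds by a fixed
affine scheme modulo 2³¹−1, so artifacts are bit-identical across
re-runs and every written artifact records the seed plus a hash of its
configuration.

## Problem sizes used in the test suite

The suite favours the smallest sizes at which the statistical checks
are sharp: 100-s single-rate sessions for Poisson rate recovery (3
standard errors), 120-s 20-channel LFP sessions (≈ 239 analysis
windows) for trigger hit/false-alarm rates, 100 independent windows for
PSD flatness (5%), one-minute calibration blocks for decoder tests, and
30 pooled trials per control mode for the release-time direction check.

## Known limitations

* No day-to-day nonstationarity, fatigue, visual neglect, or reaction
  time variability in the generators; determinism is a feature for
  testing and a departure from clinical reality.
* LFP lacks spectral structure beyond a flat band level; the trigger's
  robustness to line noise or broadband artifacts is untested by design
  (artifact rejection is out of scope).
* Only the hand motor and the vertical cursor axis are simulated; elbow
  control exists as decision rules but drives no plant.
* The myoelectric spasticity model is a one-parameter caricature chosen
  to make the control-mode comparison directionally meaningful, not a
  biomechanical model of hypertonia.
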