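#' EMG simulation configuration
#'
#' The orthosis consumes four rectified-RMS EMG envelopes: wrist
#' flexors, wrist extensors, biceps, triceps.  Post-stroke structure is
#' injected through two couplings: `cocontraction_gain` drives the wrist
#' extensor from the wrist-flexor drive (simultaneous agonist-antagonist
#' contraction) and `synergy_gain` drives the biceps from the
#' wrist-flexor drive (abnormal flexor synergy).
#'
#' @param baseline resting envelope level, arbitrary volts (default 0.1)
#' @param drive_gain envelope units per unit intent (default 1)
#' @param synergy_gain wrist-flexor to biceps coupling (default 0.6)
#' @param cocontraction_gain wrist-flexor to wrist-extensor coupling
#'   (default 0.8)
#' @param noise_sd envelope noise SD (default 0.05)
#' @param step envelope grid step, seconds (default 0.1, i.e. 100 ms)
#' @return object of class `emg_sim_config`
#' @export
emg_sim_config <- function(baseline = 0.1, drive_gain = 1,
                           synergy_gain = 0.6, cocontraction_gain = 0.8,
                           noise_sd = 0.05, step = 0.1) {
  if (synergy_gain < 0 || cocontraction_gain < 0)
    stop("coupling gains must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(baseline = baseline, drive_gain = drive_gain,
                 synergy_gain = synergy_gain,
                 cocontraction_gain = cocontraction_gain,
                 noise_sd = noise_sd, step = step),
            class = "emg_sim_config")
}

#' Generate 4-channel rectified-RMS EMG envelopes
#'
#' Envelopes are generated directly on a 100-ms grid (the orthosis
#' consumes rectified RMS, so no raw-EMG stage is modeled).  The
#' wrist-flexor drive is `hand_intent` plus noise; the extensor drive is
#' `cocontraction_gain` times the flexor drive plus its own noise; the
#' biceps drive adds `synergy_gain` times the flexor drive to the elbow
#' flexion intent; the triceps drive follows elbow extension intent.
#' All envelopes are `baseline + drive_gain * drive`, clamped at zero
#' (rectified RMS is non-negative).
#'
#' @param intent an [intent_trace][make_intent_trace]
#' @param cfg an [emg_sim_config()]
#' @param seed integer seed (mandatory)
#' @return list with `times` and matrix `envelopes` (4 x n, rows
#'   wrist_flexor, wrist_extensor, biceps, triceps)
#' @export
generate_emg <- function(intent, cfg, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(intent, "intent_trace"), inherits(cfg, "emg_sim_config"))
  total <- length(intent$times) * intent$step
  n <- max(1L, round(total / cfg$step))
  tt <- (seq_len(n) - 1L) * cfg$step
  h <- intent_at(intent, tt)
  eidx <- pmin(length(intent$elbow_intent), pmax(1L, floor(tt / intent$step) + 1L))
  e <- intent$elbow_intent[eidx]
  with_seed(seed, {
    nz <- function() stats::rnorm(n, sd = cfg$noise_sd)
    f_drive <- h + nz()
    x_drive <- cfg$cocontraction_gain * f_drive + nz()
    b_drive <- pmax(e, 0) + cfg$synergy_gain * f_drive + nz()
    t_drive <- pmax(-e, 0) + nz()
    env <- rbind(
      wrist_flexor   = pmax(0, cfg$baseline + cfg$drive_gain * f_drive),
      wrist_extensor = pmax(0, cfg$baseline + cfg$drive_gain * x_drive),
      biceps         = pmax(0, cfg$baseline + cfg$drive_gain * b_drive),
      triceps        = pmax(0, cfg$baseline + cfg$drive_gain * t_drive)
    )
    list(times = tt, envelopes = env, cfg = cfg)
  })
}
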