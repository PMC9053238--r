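#' Closed-loop grasp-move-release scenario configuration
#'
#' Describes the simulated functional task: the hand (initially open)
#' closes on a presented object, transports it, and — once over the
#' drop bin — must re-open far enough to release it; the cycle repeats.
#' The release time is the interval from the over-bin event to the
#' aperture crossing the release threshold.
#'
#' @param n_trials grasp-move-release cycles (default 5, as performed
#'   five-in-a-row)
#' @param transport_s transport phase length, seconds (default 2)
#' @param inter_trial_s pause between cycles, seconds (default 1)
#' @param grasp_aperture aperture at/below which the object counts as
#'   grasped (default 0.2)
#' @param release_aperture aperture at/above which the object drops
#'   (default 0.8)
#' @param motor_rate orthosis motor speed, aperture/s (default 2)
#' @param timeout_s per-phase timeout; a phase that times out yields an
#'   incomplete cycle (default 30)
#' @param flex_th,ext_th myoelectric thresholds (defaults 0.5)
#' @param flex_active flexor envelope during active closing (default 1)
#' @param relax_level flexor envelope floor during relaxed opening
#'   without spasticity (default 0.05)
#' @param spasticity enable the spasticity coupling: during attempted
#'   opening the flexor envelope relaxes only slowly toward an elevated
#'   floor, so the motors oppose the abnormal flexor tone (default TRUE)
#' @param spast_level elevated flexor floor with spasticity on
#'   (default 0.45, just below `flex_th`)
#' @param tau_relax flexor relaxation time constant, seconds (default 1)
#' @param emg_noise_sd flexor envelope noise SD (default 0.05)
#' @param at decoder-output discretization threshold AT (default 0.5)
#' @param bin_width BCI filter bin width, seconds (default 0.2)
#' @param calib_duration calibration block length for the on-the-fly
#'   decoder fit, seconds (default 60)
#' @param trigger_threshold training-less trigger threshold, V^2/Hz
#'   (default 10)
#' @param lfp_channels channels simulated for the training-less mode
#'   (default 4)
#' @param rest_band_power,move_band_power LFP band-power levels for the
#'   training-less mode, V^2/Hz (defaults 1.5, 12)
#' @return object of class `closed_loop_scenario`
#' @export
closed_loop_scenario <- function(n_trials = 5, transport_s = 2,
                                 inter_trial_s = 1, grasp_aperture = 0.2,
                                 release_aperture = 0.8, motor_rate = 2,
                                 timeout_s = 30,
                                 flex_th = 0.5, ext_th = 0.5,
                                 flex_active = 1, relax_level = 0.05,
                                 spasticity = TRUE, spast_level = 0.45,
                                 tau_relax = 1, emg_noise_sd = 0.05,
                                 at = 0.5, bin_width = 0.2,
                                 calib_duration = 60,
                                 trigger_threshold = 10, lfp_channels = 4,
                                 rest_band_power = 1.5, move_band_power = 12) {
  structure(as.list(environment()), class = "closed_loop_scenario")
}

#' Run a simulated closed-loop orthosis session
#'
#' Wires a synthetic participant through the selected control pathway —
#' myoelectric thresholds, the calibrated BCI linear filter with
#' single-threshold discretization, the training-less band-power
#' trigger, or an oracle that issues perfect commands — into the
#' orthosis plant, executing the grasp-move-release scenario and
#' logging commands, apertures and task events.
#'
#' Update rates follow each pathway's natural cadence: 10 Hz for the
#' myoelectric modes (RMS envelopes), 5 Hz for the BCI filter (200-ms
#' count bins), 2 Hz for the training-less trigger (500-ms band-power
#' updates).
#'
#' @param mode one of `"myoelectric"`, `"bci_filter"`,
#'   `"bci_trainingless"`, `"oracle"`
#' @param seed integer seed (mandatory)
#' @param scenario a [closed_loop_scenario()]
#' @param decoder optional pre-fitted [linear_filter][fit_linear_filter]
#'   for `bci_filter` mode; when NULL one is calibrated on the fly via
#'   [two_stage_calibration()]
#' @return object of class `session_log`: data.frame with columns
#'   `time`, `mode`, `trial`, `command`, `aperture`, `event`
#' @export
run_closed_loop <- function(mode, seed, scenario = closed_loop_scenario(),
                            decoder = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  modes <- c("myoelectric", "bci_filter", "bci_trainingless", "oracle")
  if (!mode %in% modes)
    stop("unknown mode: ", mode, " (expected one of ",
         paste(modes, collapse = ", "), ")")
  sc <- scenario

  participant <- NULL
  if (mode == "bci_filter") {
    n_ch <- if (!is.null(decoder)) decoder$n_channels else 40
    participant <- synthetic_participant(n_channels = n_ch,
                                         seed = derive_seed(seed, 31))
    if (is.null(decoder)) {
      cal <- two_stage_calibration(participant, seed = derive_seed(seed, 32),
                                   duration = sc$calib_duration)
      decoder <- cal$model
    }
  }

  with_seed(derive_seed(seed, 41), {
    ctrl <- switch(mode,
      oracle = oracle_controller(),
      myoelectric = myo_controller(sc),
      bci_filter = bci_filter_controller(sc, decoder, participant),
      bci_trainingless = trainingless_controller(sc))
    run_task_schedule(mode, ctrl, sc)
  })
}

# ---- controllers: closures mapping (close_intent, t) -> command ----------

oracle_controller <- function() {
  function(close_intent, t) if (close_intent > 0) CMD_CLOSE else CMD_OPEN
}

# CLOSE-mode myoelectric control: flexor envelope is high while closing
# and relaxes exponentially toward a floor while opening; with spasticity
# the floor sits just below the threshold, delaying the release
myo_controller <- function(sc) {
  env <- new.env()
  env$last_close <- TRUE
  env$t_open <- 0
  floor_level <- if (sc$spasticity) sc$spast_level else sc$relax_level
  function(close_intent, t) {
    closing <- close_intent > 0
    if (env$last_close && !closing) env$t_open <- t
    env$last_close <- closing
    f <- if (closing) sc$flex_active else
      floor_level + (sc$flex_active - floor_level) *
        exp(-(t - env$t_open) / sc$tau_relax)
    f <- max(0, f + stats::rnorm(1, sd = sc$emg_noise_sd))
    emg_close_mode(f, sc$flex_th)
  }
}

# calibrated linear filter on binned Poisson counts, discretized at AT
bci_filter_controller <- function(sc, decoder, participant) {
  env <- new.env()
  env$history <- NULL
  lags <- if (is.null(decoder$lags)) 0:4 else decoder$lags
  max_lag <- max(lags)
  function(close_intent, t) {
    cts <- participant_counts(participant, close_intent, 0, sc$bin_width)
    env$history <- cbind(env$history, cts)
    if (ncol(env$history) > max_lag + 1L)
      env$history <- env$history[, (ncol(env$history) - max_lag):ncol(env$history), drop = FALSE]
    if (ncol(env$history) <= max_lag) return(CMD_OPEN)
    tcur <- ncol(env$history)
    row <- as.numeric(env$history[, tcur - lags])
    x <- predict(decoder, matrix(row, nrow = 1))
    discretize_single_threshold(x, sc$at)
  }
}

# training-less trigger: per-update white-noise LFP segments at the
# intent-dependent PSD level; band power of the rolling 1-s window
trainingless_controller <- function(sc) {
  fs <- 2000
  seg_n <- fs / 2  # 500-ms segments; window = previous + current segment
  env <- new.env()
  env$prev <- NULL
  cfg <- band_power_config()
  function(close_intent, t) {
    psd <- sc$rest_band_power +
      (sc$move_band_power - sc$rest_band_power) * close_intent
    seg <- matrix(stats::rnorm(sc$lfp_channels * seg_n, sd = sqrt(psd * fs / 2)),
                  nrow = sc$lfp_channels)
    win <- if (is.null(env$prev)) cbind(seg, seg) else cbind(env$prev, seg)
    env$prev <- seg
    bp <- mean(vapply(seq_len(nrow(win)), function(ch)
      periodogram_band_power(win[ch, ], fs, cfg)$band_power, 0))
    trainingless_trigger(bp, sc$trigger_threshold)
  }
}

# ---- task schedule -------------------------------------------------------

run_task_schedule <- function(mode, ctrl, sc) {
  dt <- switch(mode, myoelectric = 0.1, bci_filter = sc$bin_width,
               bci_trainingless = 0.5, oracle = 0.1)
  rows <- list()
  t <- 0
  aperture <- 1
  add <- function(cmd, ap, trial, event = NA_character_, time = t) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time = time, mode = mode, trial = trial, command = cmd,
      aperture = ap, event = event, stringsAsFactors = FALSE)
  }
  step <- function(close_intent, trial) {
    cmd <- ctrl(close_intent, t)
    prev <- aperture
    aperture <<- orthosis_step(aperture, cmd, dt, sc$motor_rate)
    t <<- t + dt
    add(cmd, aperture, trial)
    c(prev = prev, new = aperture)
  }
  for (trial in seq_len(sc$n_trials)) {
    add(NA_character_, aperture, trial, "object_presented")
    # grasp: close until the object is held
    t_phase <- t
    grasped <- FALSE
    while (t - t_phase < sc$timeout_s) {
      step(1, trial)
      if (aperture <= sc$grasp_aperture) { grasped <- TRUE; break }
    }
    if (!grasped) { add(NA_character_, aperture, trial, "trial_timeout"); next }
    add(NA_character_, aperture, trial, "grasp_complete")
    # transport with sustained closing intent
    for (k in seq_len(round(sc$transport_s / dt))) step(1, trial)
    add(NA_character_, aperture, trial, "over_bin")
    # release: open until the drop threshold is crossed
    t_phase <- t
    released <- FALSE
    while (t - t_phase < sc$timeout_s) {
      ap <- step(0, trial)
      if (aperture >= sc$release_aperture) {
        # linear interpolation inside the crossing step
        frac <- (sc$release_aperture - ap["prev"]) / (ap["new"] - ap["prev"])
        add(NA_character_, sc$release_aperture, trial, "release",
            time = t - dt + frac * dt)
        released <- TRUE
        break
      }
    }
    if (!released) add(NA_character_, aperture, trial, "trial_timeout")
    for (k in seq_len(round(sc$inter_trial_s / dt))) step(0, trial)
  }
  log <- do.call(rbind, rows)
  log <- log[order(log$time), ]
  rownames(log) <- NULL
  class(log) <- c("session_log", "data.frame")
  log
}

#' @export
print.session_log <- function(x, ...) {
  ev <- x$event[!is.na(x$event)]
  cat(sprintf("Session log: mode %s, %.1f s, %d trials, events: %s\n",
              x$mode[1], max(x$time), max(x$trial),
              paste(sprintf("%s x%d", names(table(ev)), table(ev)), collapse = ", ")))
  invisible(x)
}

#' Write a session log as JSON lines
#'
#' One JSON object per row (timestamp, mode, trial, command, aperture,
#' event), the interchange format for simulated sessions.
#'
#' @param log a `session_log`
#' @param path file path
#' @export
write_session_log_jsonl <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_session_log_jsonl
#' @export
read_session_log_jsonl <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    r <- jsonlite::fromJSON(l)
    r[vapply(r, is.null, TRUE)] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, rows)
  class(log) <- c("session_log", "data.frame")
  log
}
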