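small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_channels = 4, n_active_channels = 2,
                   lfp_modulated_channels = 1:2)
  do.call(neural_sim_config,
          c(args, defaults[setdiff(names(defaults), names(args))]))
}

test_that("untuned channels recover the baseline Poisson rate", {
  it <- make_intent_trace(list(list("rest", 100)), seed = 1)
  cfg <- small_cfg(baseline_rate = 10, tuning_gain = 0, n_active_channels = 0)
  spk <- generate_spike_trains(it, cfg, seed = 42)
  for (ch in 1:4) {
    n <- length(spk$spike_times[[ch]])
    # Poisson(1000): empirical rate within 3 standard errors of 10 Hz
    expect_lt(abs(n / 100 - 10), 3 * sqrt(10 / 100))
  }
})

test_that("zero-rate processes emit no spikes and bad rates error", {
  it <- make_intent_trace(list(list("rest", 10)), seed = 1)
  cfg <- small_cfg(baseline_rate = 0, tuning_gain = 0, n_active_channels = 0)
  spk <- generate_spike_trains(it, cfg, seed = 1)
  expect_true(all(lengths(spk$spike_times) == 0))
  expect_error(neural_sim_config(baseline_rate = -1), "baseline_rate")
})

test_that("epoch-wise rates recover baseline and baseline + gain", {
  it <- make_intent_trace(alternating_protocol(move_s = 10, rest_s = 10,
                                               n_cycles = 6), seed = 1)
  cfg <- small_cfg(baseline_rate = 10, tuning_gain = 20)
  spk <- generate_spike_trains(it, cfg, seed = 7)
  st <- spk$spike_times[[1]]  # gain +20 channel
  r_rest <- epoch_rate(st, it, "rest")
  r_move <- epoch_rate(st, it, "attempt_close")
  expect_lt(abs(r_rest - 10), 3 * sqrt(10 / 60))
  expect_lt(abs(r_move - 30), 3 * sqrt(30 / 60))
  # exactly n_active_channels carry tuning; spikes stay within the span
  expect_equal(sum(spk$gains != 0), cfg$n_active_channels)
  expect_true(all(unlist(spk$spike_times) >= 0 &
                    unlist(spk$spike_times) <= 120))
})

test_that("generators are bit-identical under identical config and seed", {
  it <- make_intent_trace(alternating_protocol(n_cycles = 1), seed = 2)
  cfg <- small_cfg()
  expect_identical(generate_spike_trains(it, cfg, seed = 9),
                   generate_spike_trains(it, cfg, seed = 9))
  expect_identical(generate_lfp(it, cfg, seed = 9, n_channels = 2),
                   generate_lfp(it, cfg, seed = 9, n_channels = 2))
  expect_identical(generate_emg(it, emg_sim_config(), seed = 9),
                   generate_emg(it, emg_sim_config(), seed = 9))
})

test_that("LFP band power is calibrated to the configured PSD levels", {
  it <- make_intent_trace(list(list("rest", 15)), seed = 1)
  cfg <- small_cfg(rest_band_power = 1, move_band_power = 12)
  lfp <- generate_lfp(it, cfg, seed = 3, n_channels = 2)
  stream <- rolling_feature_stream(lfp)
  # mean measured 100-500 Hz power within 20% of the configured 1 V^2/Hz
  expect_lt(abs(mean(stream$values) - 1), 0.2)
  # independent check of one window against the brute-force DFT oracle
  win <- lfp$data[1, 1:2000]
  expect_equal(periodogram_band_power(win, 2000)$band_power,
               oracle_band_power_dft(win, 2000)$band_power, tolerance = 1e-10)
})

test_that("null LFP config yields zero band power and Nyquist is enforced", {
  it <- make_intent_trace(list(list("rest", 3)), seed = 1)
  cfg <- small_cfg(rest_band_power = 0, move_band_power = 1)
  lfp <- generate_lfp(it, cfg, seed = 4, n_channels = 4)
  # unmodulated channels get the resting level (here exactly zero signal)
  expect_true(all(lfp$data[3:4, ] == 0))
  expect_equal(rolling_feature_stream(lfp)$values[3, ], rep(0, 5))
  cfg_bad <- small_cfg(lfp_fs = 500)
  expect_error(generate_lfp(it, cfg_bad, seed = 1), "Nyquist")
})

test_that("movement epochs push band power over the 10 V^2/Hz trigger", {
  it <- make_intent_trace(alternating_protocol(move_s = 5, rest_s = 5,
                                               n_cycles = 4), seed = 1)
  cfg <- small_cfg(rest_band_power = 1.5, move_band_power = 12)
  lfp <- generate_lfp(it, cfg, seed = 5, n_channels = 2)
  stream <- rolling_feature_stream(lfp)
  cls <- bcisim:::window_classes(stream, it)
  mv <- colMeans(stream$values[1:2, cls == "move", drop = FALSE])
  expect_gt(mean(mv > 10), 0.9)
})

test_that("EMG couplings imprint the expected correlation signs", {
  it <- make_intent_trace(list(list("rest", 300)), seed = 1)
  indep <- emg_sim_config(synergy_gain = 0, cocontraction_gain = 0)
  e0 <- generate_emg(it, indep, seed = 11)
  expect_lt(abs(cor(e0$envelopes["wrist_flexor", ], e0$envelopes["biceps", ])), 0.2)
  cc <- generate_emg(it, emg_sim_config(), seed = 11)
  expect_gt(cor(cc$envelopes["wrist_flexor", ], cc$envelopes["wrist_extensor", ]), 0.5)
  expect_gt(cor(cc$envelopes["wrist_flexor", ], cc$envelopes["biceps", ]), 0)
  expect_true(all(cc$envelopes >= 0))
})

test_that("noise-free resting EMG is a constant baseline", {
  it <- make_intent_trace(list(list("rest", 10)), seed = 1)
  cfg <- emg_sim_config(noise_sd = 0)
  e <- generate_emg(it, cfg, seed = 1)
  expect_true(all(e$envelopes == cfg$baseline))
  expect_error(emg_sim_config(cocontraction_gain = -1), "gains")
})
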