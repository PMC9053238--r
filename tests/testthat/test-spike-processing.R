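test_that("RMS threshold scales with the signal and flags silence", {
  set.seed(1)
  v <- rnorm(5000)
  th <- compute_rms_threshold(v, fs = 1000, rms_multiplier = -4.5)
  expect_lt(abs(th - (-4.5)), 0.2)  # RMS of standard noise ~ 1
  expect_lt(th, 0)
  expect_equal(compute_rms_threshold(3 * v, fs = 1000), 3 * th)
  expect_warning(th0 <- compute_rms_threshold(rep(0, 2000), fs = 1000),
                 "all-zero")
  expect_equal(th0, 0)
  expect_error(compute_rms_threshold(v[1:10], fs = 1000), "1 s")
  expect_error(compute_rms_threshold(v, fs = 1000, rms_multiplier = 0), "nonzero")
})

test_that("threshold crossings recover injected template spikes", {
  it <- make_intent_trace(list(list("rest", 5)), seed = 1)
  cfg <- neural_sim_config(n_channels = 1, n_active_channels = 0,
                           tuning_gain = 0, baseline_rate = 10,
                           spikeband_fs = 10000, spike_snr = 10,
                           lfp_modulated_channels = 1)
  spk <- generate_spike_trains(it, cfg, seed = 3, render_channels = 1)
  truth <- spk$spike_times[[1]]
  v <- spk$recording$data[1, ]
  th <- compute_rms_threshold(v, fs = 10000)
  det <- detect_spikes(v, fs = 10000, threshold = th)
  matched <- vapply(truth, function(s) any(abs(det - s) <= 5e-4), TRUE)
  false_pos <- vapply(det, function(d) all(abs(truth - d) > 5e-4), TRUE)
  expect_gte(mean(matched), 0.95)
  expect_lte(sum(false_pos), ceiling(0.05 * length(truth)))
})

test_that("detection respects polarity, silence and lockout", {
  expect_length(detect_spikes(rnorm(1000, sd = 0.1), 1000, threshold = -1), 0)
  # two crossings 0.4 ms apart with 1 ms lockout collapse to one spike
  v <- rep(0, 100)
  v[c(10, 14)] <- -2
  expect_length(detect_spikes(v, fs = 10000, threshold = -1, lockout = 0.001), 1)
  expect_length(detect_spikes(v, fs = 10000, threshold = -1, lockout = 0), 2)
  expect_error(detect_spikes(v, 10000, threshold = 0), "nonzero")
})

test_that("binning uses half-open edges and conserves counts", {
  b <- bin_spike_counts(list(c(0.10, 0.19, 0.20)), bin_width = 0.2, span = c(0, 0.4))
  expect_equal(b$counts[1, ], c(2, 1))
  empty <- bin_spike_counts(list(numeric(0), numeric(0)), span = c(0, 1))
  expect_true(all(empty$counts == 0))
  expect_equal(dim(empty$counts), c(2, 5))
  set.seed(4)
  st <- list(sort(runif(1000, 0, 50)), sort(runif(500, 0, 50)))
  b2 <- bin_spike_counts(st, span = c(0, 50))
  expect_equal(sum(b2$counts), 1500)          # conservation
  expect_true(all(b2$counts >= 0))
  expect_error(bin_spike_counts(list(c(1, 61)), span = c(0, 60)), "outside span")
})

test_that("leaky integrator matches its closed-form step response", {
  cts <- matrix(1, 1, 400)
  r <- leaky_integrate(cts, tau = 0.2, bin_width = 0.2)
  expect_equal(r$values[1, 400], 1 / (1 - exp(-1)), tolerance = 1e-9)
  # no-memory limit: tiny tau returns the raw counts
  r2 <- leaky_integrate(matrix(c(3, 0, 5, 1), 1), tau = 0.2 / 100, bin_width = 0.2)
  expect_equal(r2$values[1, ], c(3, 0, 5, 1), tolerance = 1e-9)
  expect_true(all(leaky_integrate(matrix(0, 2, 10))$values == 0))
  expect_error(leaky_integrate(cts, tau = 0), "tau")
})

test_that("population sum is linear and follows intent on synthetic sessions", {
  cts <- matrix(rpois(40, 3), 2, 20)
  cts[2, ] <- cts[1, ]
  r <- leaky_integrate(cts)
  expect_equal(population_sum(r, normalize = FALSE),
               2 * r$values[1, ])
  rn <- population_sum(leaky_integrate(cts[1, , drop = FALSE]), normalize = TRUE)
  expect_equal(max(rn), 1)

  it <- make_intent_trace(alternating_protocol(move_s = 5, rest_s = 5,
                                               n_cycles = 6), seed = 1)
  cfg <- neural_sim_config(n_channels = 8, n_active_channels = 8,
                           baseline_rate = 5,
                           tuning_gain = rep(30, 8),
                           lfp_modulated_channels = 1:2)
  spk <- generate_spike_trains(it, cfg, seed = 21)
  b <- bin_spike_counts(spk$spike_times, span = c(0, 60))
  pop <- population_sum(leaky_integrate(b), normalize = TRUE)
  h <- intent_bin <- colMeans(matrix(it$hand_intent, nrow = 10))  # 200-ms means
  expect_gt(cor(pop, h), 0.5)
})

test_that("binned counts round-trip through CSV", {
  b <- bin_spike_counts(list(c(0.1, 0.5), c(0.3)), span = c(0, 1))
  path <- tempfile(fileext = ".csv")
  write_binned_counts_csv(b, path)
  b2 <- read_binned_counts_csv(path)
  expect_equal(unname(b2$counts), unname(b$counts))
  expect_equal(b2$bin_width, b$bin_width)
})
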