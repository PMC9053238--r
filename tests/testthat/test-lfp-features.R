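test_that("periodogram is exact on null signals and satisfies Parseval", {
  z <- periodogram_band_power(rep(0, 2000), 2000)
  expect_true(all(z$bin_power == 0))
  set.seed(8)
  x <- rnorm(2000, sd = 2)
  pg <- periodogram_band_power(x, 2000)
  # Parseval: integrated one-sided PSD equals the mean squared signal
  df <- 2000 / length(x)
  expect_equal(sum(pg$psd) * df, mean(x^2), tolerance = 1e-6)
})

test_that("white-noise PSD is flat at 2 sigma^2 / fs", {
  set.seed(9)
  sigma2 <- 4
  vals <- replicate(100, {
    periodogram_band_power(rnorm(2000, sd = sqrt(sigma2)), 2000)$bin_power
  })
  expected <- 2 * sigma2 / 2000
  expect_true(all(abs(rowMeans(vals) - expected) / expected < 0.05))
})

test_that("a 250 Hz tone lands entirely in the 200-250 Hz bin", {
  tt <- (0:1999) / 2000
  x <- sin(2 * pi * 250 * tt)
  pg <- periodogram_band_power(x, 2000)
  orc <- oracle_band_power_dft(x, 2000)
  expect_equal(pg$bin_power, orc$bin_power, tolerance = 1e-9)
  expect_equal(which.max(pg$bin_power), 3)       # the 200-250 bin
  expect_lt(sum(pg$bin_power[-3]) / pg$bin_power[3], 1e-10)
  expect_equal(pg$band_power, pg$bin_power[3] / 8, tolerance = 1e-12)
})

test_that("band power ignores out-of-band components", {
  set.seed(10)
  x <- rnorm(2000)
  tt <- (0:1999) / 2000
  x_tones <- x + 3 * sin(2 * pi * 50 * tt) + 3 * sin(2 * pi * 700 * tt)
  expect_equal(periodogram_band_power(x_tones, 2000)$band_power,
               periodogram_band_power(x, 2000)$band_power, tolerance = 1e-6)
})

test_that("rolling windows are end-aligned with 500-ms updates", {
  rec <- continuous_recording(matrix(rnorm(20000), 1), fs = 2000)
  st <- rolling_feature_stream(rec)
  expect_equal(ncol(st$values), 19)              # floor((10-1)/0.5)+1
  expect_equal(st$times[1], 1)
  expect_equal(diff(st$times), rep(0.5, 18))
  # stationary signal: all windows near the common level
  expect_lt(diff(range(st$values)) / mean(st$values), 0.5)
  expect_lt(sd(st$values) / mean(st$values), 0.1)
  expect_error(rolling_feature_stream(
    continuous_recording(matrix(rnorm(100), 1), fs = 2000)), "shorter")
})

test_that("streams do not concatenate across recording seams", {
  set.seed(11)
  a <- matrix(rnorm(4000), 1)
  b <- matrix(rnorm(4000), 1)
  joint <- rolling_feature_stream(continuous_recording(cbind(a, b), 2000))
  sep <- cbind(rolling_feature_stream(continuous_recording(a, 2000))$values,
               rolling_feature_stream(continuous_recording(b, 2000))$values)
  # the boundary-straddling windows of the joint stream have no separate
  # counterpart: window counts differ
  expect_gt(ncol(joint$values), ncol(sep))
})

test_that("modulated channels are recovered by the neuromodulation ranking", {
  it <- make_intent_trace(alternating_protocol(move_s = 5, rest_s = 5,
                                               n_cycles = 6), seed = 1)
  cfg <- neural_sim_config(n_channels = 12, n_active_channels = 0,
                           tuning_gain = 0,
                           rest_band_power = 1.5, move_band_power = 12,
                           lfp_modulated_channels = c(2, 5, 9, 11))
  lfp <- generate_lfp(it, cfg, seed = 13, n_channels = 12)
  st <- rolling_feature_stream(lfp)
  top <- rank_neuromodulated_channels(st, it, n = 4)
  expect_setequal(top, c(2, 5, 9, 11))
  expect_equal(rank_neuromodulated_channels(st, it, n = 0), integer(0))
  # all-identical channels: deterministic tie-break by index
  flat <- st
  flat$values <- matrix(1, 6, ncol(st$values))
  expect_equal(rank_neuromodulated_channels(flat, it, n = 3), 1:3)
  # single-class labels error
  rest_it <- make_intent_trace(list(list("rest", 12)), seed = 1)
  rest_lfp <- generate_lfp(rest_it, cfg, seed = 14, n_channels = 2)
  rest_st <- rolling_feature_stream(rest_lfp)
  expect_error(rank_neuromodulated_channels(rest_st, rest_it, 2), "both")
})

test_that("the trigger applies a strict 10 V^2/Hz rule", {
  expect_equal(trainingless_trigger(c(2, 5, 11, 9, 15)),
               c("open", "open", "close", "open", "close"))
  expect_equal(trainingless_trigger(10), "open")  # strict inequality
  expect_error(trainingless_trigger(5, threshold = 0), "> 0")
})

test_that("raising the threshold never adds close windows", {
  set.seed(15)
  v <- runif(200, 0, 20)
  lo <- trainingless_trigger(v, threshold = 8)
  hi <- trainingless_trigger(v, threshold = 12)
  expect_true(all(!(hi == "close" & lo == "open")))
  expect_lte(sum(hi == "close"), sum(lo == "close"))
})

test_that("rest-only sessions essentially never trigger closure", {
  it <- make_intent_trace(list(list("rest", 60)), seed = 1)
  cfg <- neural_sim_config(n_channels = 4, n_active_channels = 0,
                           tuning_gain = 0, rest_band_power = 3,
                           move_band_power = 12, lfp_modulated_channels = 1:4)
  lfp <- generate_lfp(it, cfg, seed = 16, n_channels = 4)
  st <- rolling_feature_stream(lfp)
  cmds <- trainingless_trigger(colMeans(st$values))
  expect_gte(mean(cmds == "open"), 0.99)
})

test_that("feature streams round-trip through CSV", {
  rec <- continuous_recording(matrix(rnorm(8000), 2), fs = 2000)
  st <- rolling_feature_stream(rec)
  path <- tempfile(fileext = ".csv")
  write_feature_stream_csv(st, path)
  st2 <- read_feature_stream_csv(path)
  expect_equal(unname(st2$values), unname(st$values), tolerance = 1e-12)
  expect_equal(st2$cfg$band_lo, 100)
  expect_equal(st2$cfg$update, 0.5)
})
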