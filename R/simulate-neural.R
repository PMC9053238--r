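#' Neural simulation configuration
#'
#' Describes the synthetic electrode grid: how many channels exist, how
#' many carry intent-tuned units, the baseline and per-channel tuning of
#' the firing-rate model, the sampling rates of the rendered signals, and
#' the resting / movement levels of high-gamma (100-500 Hz) LFP band
#' power.  Defaults mirror a 256-channel implant with units on 87
#' channels and LFP band power rising from a resting 0.5-3 V^2/Hz
#' baseline to above 10 V^2/Hz during attempted movement.
#'
#' @param n_channels total electrode channels (default 256)
#' @param n_active_channels channels with nonzero tuning (default 87)
#' @param baseline_rate baseline firing rate, spikes/s (default 10)
#' @param tuning_gain spikes/s per unit hand intent: either a scalar used
#'   (with alternating sign) for every active channel, or a length
#'   `n_channels` vector of per-channel signed gains
#' @param lfp_fs LFP sampling rate, Hz (default 2000)
#' @param spikeband_fs spike-band sampling rate, Hz (default 30000)
#' @param rest_band_power resting 100-500 Hz PSD level, V^2/Hz (default 1.5)
#' @param move_band_power movement 100-500 Hz PSD level, V^2/Hz (default 12)
#' @param lfp_modulated_channels indices of channels whose LFP power is
#'   intent-modulated (default first 20)
#' @param noise_sd spike-band additive noise SD, volts (default 1e-5)
#' @param spike_snr spike template peak amplitude as a multiple of
#'   `noise_sd` (default 10)
#' @return object of class `neural_sim_config`
#' @export
neural_sim_config <- function(n_channels = 256, n_active_channels = 87,
                              baseline_rate = 10, tuning_gain = 20,
                              lfp_fs = 2000, spikeband_fs = 30000,
                              rest_band_power = 1.5, move_band_power = 12,
                              lfp_modulated_channels = seq_len(min(20, n_channels)),
                              noise_sd = 1e-5, spike_snr = 10) {
  if (n_active_channels > n_channels)
    stop("n_active_channels must be <= n_channels")
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (rest_band_power >= move_band_power)
    stop("rest_band_power must be < move_band_power")
  if (length(tuning_gain) == 1L) {
    g <- numeric(n_channels)
    if (n_active_channels > 0) {
      sgn <- rep_len(c(1, -1), n_active_channels)
      g[seq_len(n_active_channels)] <- sgn * tuning_gain
    }
    tuning_gain <- g
  } else if (length(tuning_gain) != n_channels) {
    stop("tuning_gain must be scalar or length n_channels")
  }
  structure(list(
    n_channels = n_channels, n_active_channels = n_active_channels,
    baseline_rate = baseline_rate, tuning_gain = tuning_gain,
    lfp_fs = lfp_fs, spikeband_fs = spikeband_fs,
    rest_band_power = rest_band_power, move_band_power = move_band_power,
    lfp_modulated_channels = lfp_modulated_channels,
    noise_sd = noise_sd, spike_snr = spike_snr
  ), class = "neural_sim_config")
}

#' Generate intent-modulated spike trains and spike-band voltage
#'
#' Each channel fires as an inhomogeneous Poisson process with rate
#' `rate_c(t) = baseline_rate + tuning_gain_c * hand_intent(t)`, floored
#' at zero, realized by thinning a homogeneous process at the per-channel
#' maximum rate.  Exactly `n_active_channels` channels have nonzero
#' tuning.  Optionally, spike-band voltage is rendered for a subset of
#' channels as Gaussian noise plus a stereotyped biphasic waveform
#' (negative-going first, peak amplitude `spike_snr * noise_sd`) at each
#' spike time.
#'
#' @param intent an [intent_trace][make_intent_trace]
#' @param cfg a [neural_sim_config()]
#' @param seed integer seed (mandatory)
#' @param render_channels channel indices to render voltage for
#'   (default none; rendering 30 kHz voltage for all 256 channels is
#'   rarely wanted)
#' @return list with `spike_times` (list of numeric vectors, seconds),
#'   `recording` (a [continuous_recording()] for `render_channels`, or
#'   NULL), `gains` (per-channel tuning used), `cfg`
#' @export
generate_spike_trains <- function(intent, cfg, seed, render_channels = integer(0)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(intent, "intent_trace"), inherits(cfg, "neural_sim_config"))
  if (length(intent$times) == 0L) stop("empty intent trace")
  if (cfg$baseline_rate < 0) stop("baseline_rate must be >= 0")

  total <- length(intent$times) * intent$step
  with_seed(seed, {
    spike_times <- vector("list", cfg$n_channels)
    for (ch in seq_len(cfg$n_channels)) {
      g <- cfg$tuning_gain[ch]
      rate_fun <- function(t) {
        pmax(0, cfg$baseline_rate + g * intent_at(intent, t))
      }
      rmax <- max(0, cfg$baseline_rate + max(g, 0))
      spike_times[[ch]] <- thin_poisson(rate_fun, rmax, total)
    }
    recording <- NULL
    if (length(render_channels)) {
      n <- round(total * cfg$spikeband_fs)
      mat <- matrix(stats::rnorm(length(render_channels) * n, sd = cfg$noise_sd),
                    nrow = length(render_channels))
      tmpl <- biphasic_template(cfg$spikeband_fs) * cfg$spike_snr * cfg$noise_sd
      for (i in seq_along(render_channels)) {
        st <- spike_times[[render_channels[i]]]
        for (s in st) {
          k0 <- floor(s * cfg$spikeband_fs) + 1L
          kk <- k0:(k0 + length(tmpl) - 1L)
          ok <- kk >= 1L & kk <= n
          mat[i, kk[ok]] <- mat[i, kk[ok]] + tmpl[ok]
        }
      }
      recording <- continuous_recording(mat, fs = cfg$spikeband_fs)
    }
    list(spike_times = spike_times, recording = recording,
         gains = cfg$tuning_gain, cfg = cfg)
  })
}

# piecewise-constant lookup of hand intent at arbitrary times
intent_at <- function(intent, t) {
  idx <- pmin(length(intent$hand_intent),
              pmax(1L, floor(t / intent$step) + 1L))
  intent$hand_intent[idx]
}

# inhomogeneous Poisson via thinning at envelope rate rmax over [0, total)
thin_poisson <- function(rate_fun, rmax, total) {
  if (rmax <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rmax * total)
  cand <- sort(stats::runif(n_cand, 0, total))
  if (!length(cand)) return(numeric(0))
  keep <- stats::runif(length(cand)) < rate_fun(cand) / rmax
  cand[keep]
}

# stereotyped biphasic extracellular waveform, ~1.2 ms, unit negative peak
biphasic_template <- function(fs) {
  tt <- seq(0, 0.0012, by = 1 / fs)
  w <- -exp(-((tt - 0.0003) / 0.00012)^2) + 0.45 * exp(-((tt - 0.0007) / 0.0002)^2)
  w / max(abs(w))
}

#' Generate intent-modulated local field potentials
#'
#' LFP is synthesized as piecewise-stationary white Gaussian noise whose
#' one-sided power spectral density tracks the intent trace: on
#' intent-modulated channels the PSD level is
#' `rest + (move - rest) * hand_intent(t)` V^2/Hz, on the remaining
#' channels it stays at the resting level.  Because white noise of
#' variance `sigma^2` sampled at `fs` has a flat one-sided PSD of
#' `2 sigma^2 / fs`, the per-sample SD is `sqrt(PSD(t) * fs / 2)`; the
#' configured band powers are therefore recovered by the periodogram
#' feature stream (Parseval calibration).  No oscillatory or phase
#' structure is modeled: the training-less trigger consumes power only.
#'
#' @inheritParams generate_spike_trains
#' @param n_channels number of LFP channels to generate (default
#'   `length(cfg$lfp_modulated_channels) + 4` so unmodulated channels are
#'   present); channel indices follow `cfg$lfp_modulated_channels`
#' @return a [continuous_recording()] with `n_channels` rows
#' @export
generate_lfp <- function(intent, cfg, seed,
                         n_channels = max(cfg$lfp_modulated_channels) + 4L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(intent, "intent_trace"), inherits(cfg, "neural_sim_config"))
  if (cfg$lfp_fs < 1000) stop("band exceeds Nyquist")
  total <- length(intent$times) * intent$step
  n <- round(total * cfg$lfp_fs)
  tt <- (seq_len(n) - 1L) / cfg$lfp_fs
  h <- intent_at(intent, tt)
  with_seed(seed, {
    mat <- matrix(0, nrow = n_channels, ncol = n)
    psd_rest <- cfg$rest_band_power
    psd_move <- cfg$move_band_power
    sd_rest <- sqrt(psd_rest * cfg$lfp_fs / 2)
    for (ch in seq_len(n_channels)) {
      if (ch %in% cfg$lfp_modulated_channels) {
        psd <- psd_rest + (psd_move - psd_rest) * h
        mat[ch, ] <- stats::rnorm(n, sd = sqrt(psd * cfg$lfp_fs / 2))
      } else {
        mat[ch, ] <- stats::rnorm(n, sd = sd_rest)
      }
    }
    continuous_recording(mat, fs = cfg$lfp_fs)
  })
}
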