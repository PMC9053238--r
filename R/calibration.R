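#' Synthetic cursor-tracking participant
#'
#' A generative stand-in for the decoder-calibration loop: a bank of
#' channels whose binned spike counts are Poisson with rate
#' `baseline + gain_c * y_t + feedback_gain * fb_gain_c * (y_t - pred_t)`
#' (floored at zero), where `y_t` is the displayed target cursor and
#' `pred_t` the displayed prediction cursor (0 when absent, i.e. open
#' loop).  With `feedback_gain = 0` the participant ignores the
#' prediction cursor entirely; with `feedback_gain > 0` they boost
#' activity on an error-driven subset of channels, emulating corrective
#' effort when the prediction lags the target.
#'
#' @param n_channels number of channels (default 40, the per-session
#'   decoding subset)
#' @param baseline_rate baseline rate, spikes/s (default 10)
#' @param tuning_gain per-channel target tuning; scalar (alternating
#'   sign) or length `n_channels` (default 15)
#' @param feedback_gain overall gain on the error-driven component
#'   (default 0)
#' @param seed integer seed used to draw the error-tuning pattern
#' @return object of class `synthetic_participant`
#' @export
synthetic_participant <- function(n_channels = 40, baseline_rate = 10,
                                  tuning_gain = 15, feedback_gain = 0,
                                  seed = 1) {
  if (length(tuning_gain) == 1L)
    tuning_gain <- rep_len(c(1, -1), n_channels) * tuning_gain
  stopifnot(length(tuning_gain) == n_channels, baseline_rate >= 0)
  fb_gain <- with_seed(derive_seed(seed, 11),
                       stats::rnorm(n_channels, sd = abs(mean(abs(tuning_gain)))))
  structure(list(n_channels = n_channels, baseline_rate = baseline_rate,
                 tuning_gain = tuning_gain, feedback_gain = feedback_gain,
                 fb_gain = fb_gain),
            class = "synthetic_participant")
}

# one bin of Poisson counts given target y and displayed prediction
participant_counts <- function(p, y, pred, bin_width) {
  rate <- pmax(0, p$baseline_rate + p$tuning_gain * y +
                 p$feedback_gain * p$fb_gain * (y - pred))
  stats::rpois(p$n_channels, rate * bin_width)
}

#' Two-stage cursor decoder calibration
#'
#' The filter-building protocol: (1) an open-loop block in which the
#' participant watches a target cursor sweep top-to-bottom (triangle
#' wave, 5-s half-period) for one minute while binned activity is
#' recorded, and a preliminary linear filter is fit; (2) a second
#' one-minute block in which the stage-1 prediction cursor is displayed
#' alongside the target (and fed back into the participant model), and
#' the final filter is refit on the closed-loop data.
#'
#' @param participant a [synthetic_participant()]
#' @param seed integer seed (mandatory)
#' @param duration block length, seconds (default 60)
#' @param half_period cursor half-period, seconds (default 5)
#' @param bin_width feature bin width, seconds (default 0.2)
#' @param lags lag taps in bins (default `0:4`)
#' @param ridge ridge penalty passed to [fit_linear_filter()]
#' @return list with `model` (the final stage-2
#'   [linear_filter][fit_linear_filter]), `stage1` (the preliminary
#'   model), `r_squared` (both blocks' training R^2), and the recorded
#'   blocks (`counts1`, `counts2`, `target`)
#' @export
two_stage_calibration <- function(participant, seed, duration = 60,
                                  half_period = 5, bin_width = 0.2,
                                  lags = 0:4, ridge = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(participant, "synthetic_participant"))
  n_bins <- round(duration / bin_width)
  tmid <- (seq_len(n_bins) - 0.5) * bin_width
  y <- triangle_at(tmid, half_period)

  counts1 <- with_seed(derive_seed(seed, 21), {
    vapply(seq_len(n_bins), function(t)
      participant_counts(participant, y[t], 0, bin_width),
      numeric(participant$n_channels))
  })
  asm1 <- assemble_feature_matrix(counts1, y, lags)
  stage1 <- fit_linear_filter(asm1$X, asm1$y, ridge,
                              lags = lags, n_channels = participant$n_channels)

  # closed-loop block: prediction cursor from stage-1 filter is displayed
  max_lag <- max(lags)
  counts2 <- matrix(0, participant$n_channels, n_bins)
  pred2 <- numeric(n_bins)
  with_seed(derive_seed(seed, 22), {
    for (t in seq_len(n_bins)) {
      # display is causal: while bin t accrues, the screen shows the
      # prediction decoded from the last completed bin
      pred_t <- if (t > max_lag + 1L) pred2[t - 1] else 0
      counts2[, t] <- participant_counts(participant, y[t], pred_t, bin_width)
      if (t > max_lag) {
        row <- as.numeric(counts2[, t - lags])
        pred2[t] <- predict(stage1, matrix(row, nrow = 1))
      }
    }
  })
  asm2 <- assemble_feature_matrix(counts2, y, lags)
  stage2 <- fit_linear_filter(asm2$X, asm2$y, ridge,
                              lags = lags, n_channels = participant$n_channels)
  list(model = stage2, stage1 = stage1,
       r_squared = c(stage1 = stage1$r_squared, stage2 = stage2$r_squared),
       counts1 = counts1, counts2 = counts2, target = y)
}

triangle_at <- function(t, half_period) {
  phase <- (t / half_period) %% 2
  ifelse(phase <= 1, 1 - phase, phase - 1)
}
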