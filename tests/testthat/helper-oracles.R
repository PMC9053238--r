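# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths.

# Brute-force one-sided PSD by direct DFT summation (no fft tricks beyond
# the definition), returning the mean density over each 50-Hz bin.
oracle_band_power_dft <- function(x, fs, lo = 100, hi = 500, w = 50) {
  n <- length(x)
  k_half <- 0:(floor(n / 2))
  freq <- k_half * fs / n
  psd <- vapply(k_half, function(k) {
    ex <- exp(-2i * pi * k * (0:(n - 1)) / n)
    Xk <- sum(x * ex)
    d <- if (k == 0 || (n %% 2 == 0 && k == n / 2)) 1 else 2
    d * Mod(Xk)^2 / (fs * n)
  }, 0)
  in_band <- freq >= lo & freq <= hi
  bin <- pmax(1, ceiling((freq[in_band] - lo) / w - 1e-9))
  bins <- tapply(psd[in_band], factor(bin, levels = seq_len((hi - lo) / w)), mean)
  list(bin_power = as.numeric(bins), band_power = mean(as.numeric(bins)))
}

# Pooled two-sample t from the explicit formulas, with the two-tailed p
# obtained from the regularized incomplete beta function.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- pbeta(df / (df + tstat^2), df / 2, 1 / 2)
  list(t = tstat, df = df, p = p)
}

# Conjugate-Gaussian scalar Kalman update: predictive N(a m, a^2 P + w),
# then the standard precision-weighted posterior given z = h x + N(0, q).
oracle_scalar_posterior <- function(a, w, h, q, m, P, z) {
  m_pred <- a * m
  v_pred <- a^2 * P + w
  v_post <- 1 / (1 / v_pred + h^2 / q)
  m_post <- v_post * (m_pred / v_pred + h * z / q)
  c(mean = m_post, var = v_post)
}

# Closed-loop tracking correlation of a filter model against the target,
# with the displayed prediction fed back into the participant model.
closed_loop_tracking_corr <- function(model, participant, seed,
                                      duration = 60, half_period = 5,
                                      bin_width = 0.2) {
  lags <- model$lags
  maxl <- max(lags)
  n <- round(duration / bin_width)
  y <- bcisim:::triangle_at((seq_len(n) - 0.5) * bin_width, half_period)
  cts <- matrix(0, participant$n_channels, n)
  pred <- numeric(n)
  bcisim:::with_seed(seed, {
    for (t in seq_len(n)) {
      pt <- if (t > maxl + 1) pred[t - 1] else 0
      cts[, t] <- bcisim:::participant_counts(participant, y[t], pt, bin_width)
      if (t > maxl)
        pred[t] <- predict(model, matrix(as.numeric(cts[, t - lags]), nrow = 1))
    }
  })
  cor(pred[(maxl + 1):n], y[(maxl + 1):n])
}

# Empirical rate of a spike train restricted to epochs where the given
# label holds (epoch bounds from the intent trace).
epoch_rate <- function(spikes, intent, label) {
  sel <- intent$label == label
  dur <- sum(sel) * intent$step
  idx <- pmin(length(intent$label), pmax(1L, floor(spikes / intent$step) + 1L))
  sum(sel[idx]) / dur
}
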