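#' Band-power feature configuration
#'
#' High-gamma band-power features: the one-sided periodogram of 1-second
#' rolling windows (50% overlap, so a new value every 500 ms), averaged
#' within non-overlapping 50-Hz frequency bins spanning 100-500 Hz.
#' The update interval is tied to the window and overlap
#' (`update = window * (1 - overlap_frac)`).
#'
#' @param band_lo,band_hi band edges in Hz (default 100, 500)
#' @param bin_width_hz frequency-bin width in Hz (default 50; must divide
#'   the band width)
#' @param window analysis window length, seconds (default 1)
#' @param overlap_frac fractional overlap of consecutive windows
#'   (default 0.5)
#' @return object of class `band_power_config`
#' @export
band_power_config <- function(band_lo = 100, band_hi = 500,
                              bin_width_hz = 50, window = 1,
                              overlap_frac = 0.5) {
  if (band_hi <= band_lo) stop("band_hi must be > band_lo")
  if ((band_hi - band_lo) %% bin_width_hz != 0)
    stop("band width must be divisible by bin_width_hz")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac in [0,1)")
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 bin_width_hz = bin_width_hz, window = window,
                 overlap_frac = overlap_frac,
                 update = window * (1 - overlap_frac)),
            class = "band_power_config")
}

#' One-sided rectangular-taper periodogram and band power
#'
#' Direct DFT power-spectral-density estimate with rectangular taper:
#' `P(f_k) = |X_k|^2 / (fs * N)`, doubled at all frequencies except DC
#' and Nyquist so that `sum(P) * df` equals the mean squared signal
#' (Parseval).  Band power is summarized as the mean PSD density within
#' each 50-Hz bin, then the mean over the bins.  A frequency `f` belongs
#' to bin `ceiling((f - band_lo) / bin_width_hz)` (with `f = band_lo`
#' in the first bin), so e.g. a 250 Hz tone lands in the 200-250 bin.
#'
#' @param x window samples (length must equal `cfg$window * fs`)
#' @param fs sampling rate, Hz (must be at least `2 * band_hi`)
#' @param cfg a [band_power_config()]
#' @return list with `freq` and `psd` (full one-sided periodogram,
#'   V^2/Hz), `bin_freq_lo` / `bin_power` (per 50-Hz bin mean density)
#'   and `band_power` (mean of the bin values, V^2/Hz)
#' @export
periodogram_band_power <- function(x, fs, cfg = band_power_config()) {
  if (fs < 2 * cfg$band_hi) stop("band exceeds Nyquist")
  n_expected <- round(cfg$window * fs)
  if (length(x) < n_expected) stop("window shorter than configured")
  x <- x[seq_len(n_expected)]
  n <- length(x)
  X <- stats::fft(x)
  n_half <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(n_half)])^2) / (fs * n)
  # double everything except DC and (for even n) Nyquist
  dbl <- rep(2, n_half)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_half] <- 1
  p <- p * dbl
  freq <- (seq_len(n_half) - 1L) * fs / n
  in_band <- freq >= cfg$band_lo & freq <= cfg$band_hi
  f_in <- freq[in_band]
  bin_idx <- pmax(1L, ceiling((f_in - cfg$band_lo) / cfg$bin_width_hz - 1e-9))
  n_bins <- (cfg$band_hi - cfg$band_lo) / cfg$bin_width_hz
  bin_power <- as.numeric(tapply(p[in_band], factor(bin_idx, levels = seq_len(n_bins)), mean))
  list(freq = freq, psd = p,
       bin_freq_lo = cfg$band_lo + (seq_len(n_bins) - 1L) * cfg$bin_width_hz,
       bin_power = bin_power,
       band_power = mean(bin_power))
}

#' Rolling band-power feature stream
#'
#' Applies [periodogram_band_power()] to 1-second windows sliding in
#' 500-ms steps (with the default configuration), producing one feature
#' column per update.  Windows are end-aligned (causal): the value
#' reported at time `t` uses the samples in `(t - window, t]`, as in a
#' real-time system.  A recording of duration `T` yields
#' `floor((T - window) / update) + 1` windows.
#'
#' @param recording a [continuous_recording()]
#' @param cfg a [band_power_config()]
#' @return object of class `feature_stream`: list with `times` (window
#'   end times), `values` (channels x windows band power, V^2/Hz), `cfg`
#' @export
rolling_feature_stream <- function(recording, cfg = band_power_config()) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$fs
  n_win <- round(cfg$window * fs)
  n_step <- round(cfg$update * fs)
  n <- ncol(recording$data)
  if (n < n_win) stop("recording shorter than one window")
  starts <- seq(1L, n - n_win + 1L, by = n_step)
  times <- recording$t0 + (starts + n_win - 1L) / fs
  values <- matrix(0, nrow = nrow(recording$data), ncol = length(starts))
  for (j in seq_along(starts)) {
    sl <- starts[j]:(starts[j] + n_win - 1L)
    for (ch in seq_len(nrow(recording$data))) {
      values[ch, j] <- periodogram_band_power(recording$data[ch, sl], fs, cfg)$band_power
    }
  }
  structure(list(times = times, values = values, cfg = cfg),
            class = "feature_stream")
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf("Band-power feature stream: %d channel(s) x %d windows (%g-%g Hz, %g s window, %g s update)\n",
              nrow(x$values), ncol(x$values), x$cfg$band_lo, x$cfg$band_hi,
              x$cfg$window, x$cfg$update))
  invisible(x)
}

#' Read/write feature streams as CSV
#' @param x a `feature_stream`
#' @param path file path
#' @export
write_feature_stream_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# band=%g-%g bin_width_hz=%g window=%g overlap=%g",
                     x$cfg$band_lo, x$cfg$band_hi, x$cfg$bin_width_hz,
                     x$cfg$window, x$cfg$overlap_frac), con)
  df <- data.frame(time = x$times, t(x$values))
  names(df) <- c("time", paste0("ch", seq_len(nrow(x$values))))
  utils::write.table(df, con, sep = ",", row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_stream_csv
#' @export
read_feature_stream_csv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 1L), value = TRUE)
  g <- function(key) as.numeric(sub(sprintf(".*%s=([0-9.eE+-]+).*", key), "\\1", hdr))
  band <- regmatches(hdr, regexec("band=([0-9.]+)-([0-9.]+)", hdr))[[1]]
  cfg <- band_power_config(band_lo = as.numeric(band[2]),
                           band_hi = as.numeric(band[3]),
                           bin_width_hz = g("bin_width_hz"),
                           window = g("window"), overlap_frac = g("overlap"))
  dat <- utils::read.csv(path, comment.char = "#")
  structure(list(times = dat$time, values = t(as.matrix(dat[, -1, drop = FALSE])),
                 cfg = cfg), class = "feature_stream")
}

#' Rank channels by task modulation
#'
#' Scores each channel by the absolute standardized mean difference of
#' its band-power values between movement and rest windows and returns
#' the `n` highest-scoring channels ("the most neuromodulated").  A
#' window counts as movement (rest) when it lies fully inside a movement
#' (rest) epoch of the intent trace; mixed windows are excluded.  Ties
#' break deterministically by ascending channel index.
#'
#' @param stream a [rolling_feature_stream()] result
#' @param intent the [intent_trace][make_intent_trace] the session was
#'   generated from
#' @param n number of channels to return (default 20)
#' @return integer vector of channel indices, length `n`, sorted by
#'   descending modulation score
#' @export
rank_neuromodulated_channels <- function(stream, intent, n = 20) {
  stopifnot(inherits(stream, "feature_stream"))
  if (n == 0) return(integer(0))
  cls <- window_classes(stream, intent)
  if (!any(cls == "move") || !any(cls == "rest"))
    stop("need both movement and rest windows")
  mv <- stream$values[, cls == "move", drop = FALSE]
  rs <- stream$values[, cls == "rest", drop = FALSE]
  m1 <- rowMeans(mv); m0 <- rowMeans(rs)
  v1 <- apply(mv, 1, stats::var); v0 <- apply(rs, 1, stats::var)
  n1 <- ncol(mv); n0 <- ncol(rs)
  sp <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  sp[sp == 0] <- Inf  # flat channels score 0
  score <- abs(m1 - m0) / sp
  score[!is.finite(score)] <- 0
  order(-score, seq_along(score))[seq_len(min(n, length(score)))]
}

# classify feature windows by the intent within their (t-window, t] span
window_classes <- function(stream, intent) {
  w <- stream$cfg$window
  vapply(stream$times, function(t) {
    sel <- intent$times >= (t - w) - 1e-9 & intent$times < t - 1e-9
    h <- intent$hand_intent[sel]
    if (!length(h)) return("mixed")
    if (all(h == 0)) "rest" else if (all(h > 0)) "move" else "mixed"
  }, "")
}

#' Training-less band-power trigger
#'
#' The calibration-free decoder: the hand motor closes whenever the mean
#' high-gamma band power across the selected channels exceeds the
#' threshold (strictly), and opens otherwise.  With the defaults this is
#' the 10 V^2/Hz rule applied to 500-ms updates.
#'
#' @param values scalar band-power series (already averaged across the
#'   selected channels), V^2/Hz
#' @param threshold trigger threshold, V^2/Hz (default 10; must be > 0)
#' @return character vector of motion commands, `"close"` where
#'   `value > threshold`, `"open"` elsewhere
#' @export
trainingless_trigger <- function(values, threshold = 10) {
  if (threshold <= 0) stop("threshold must be > 0")
  ifelse(values > threshold, CMD_CLOSE, CMD_OPEN)
}
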