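#' RMS-multiplier spike threshold
#'
#' Automatic per-channel detection threshold: the root mean square of the
#' spike-band voltage over the calibration segment multiplied by a signed
#' multiplier (default -4.5, the standard negative-going extracellular
#' convention).  Block RMS over the whole segment is used, not a running
#' estimate.
#'
#' @param voltage single-channel voltage samples (volts)
#' @param fs sampling rate, Hz
#' @param rms_multiplier signed multiplier (default -4.5; must be nonzero)
#' @return threshold in volts; sign equals the multiplier's sign
#' @export
compute_rms_threshold <- function(voltage, fs, rms_multiplier = -4.5) {
  if (rms_multiplier == 0) stop("rms_multiplier must be nonzero")
  if (length(voltage) < fs) stop("need at least 1 s of signal")
  rms <- sqrt(mean(voltage^2))
  if (rms == 0) {
    warning("all-zero signal: threshold is 0")
    return(0)
  }
  rms_multiplier * rms
}

#' Threshold-crossing spike detection
#'
#' Logs a spike at each sample where the signal first crosses the
#' threshold (negative-going for negative thresholds, positive-going for
#' positive ones); subsequent crossings within the lockout are
#' suppressed.
#'
#' @param voltage single-channel voltage samples
#' @param fs sampling rate, Hz
#' @param threshold detection threshold, volts (nonzero)
#' @param lockout refractory period, seconds (default 0.001)
#' @return strictly increasing spike times in seconds
#' @export
detect_spikes <- function(voltage, fs, threshold, lockout = 0.001) {
  if (threshold == 0) stop("threshold must be nonzero")
  if (lockout < 0) stop("lockout must be >= 0")
  if (threshold < 0) {
    below <- voltage < threshold
  } else {
    below <- voltage > threshold
  }
  # first sample of each crossing run
  cross <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(cross)) return(numeric(0))
  times <- (cross - 1L) / fs
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= lockout) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Bin spike times into 200-ms count windows
#'
#' Bins are contiguous, non-overlapping and half-open `[t, t + width)`,
#' covering the given span; counts are conserved (their total equals the
#' number of spikes).  A spike falling exactly on the span's right edge
#' is assigned to the last bin.
#'
#' @param spike_times list of numeric vectors (one per channel), seconds
#' @param bin_width bin width in seconds (default 0.2)
#' @param span length-2 numeric, start and end of the binned interval
#' @return object of class `binned_counts`: list with integer matrix
#'   `counts` (channels x bins), `bin_width`, `t0`, `bin_starts`
#' @export
bin_spike_counts <- function(spike_times, bin_width = 0.2, span) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  stopifnot(length(span) == 2L, span[2] > span[1], bin_width > 0)
  all_s <- unlist(spike_times, use.names = FALSE)
  if (length(all_s) && (min(all_s) < span[1] || max(all_s) > span[2]))
    stop("spike outside span")
  n_bins <- ceiling((span[2] - span[1]) / bin_width - 1e-9)
  counts <- t(vapply(spike_times, function(st) {
    if (!length(st)) return(integer(n_bins))
    idx <- pmin(n_bins, floor((st - span[1]) / bin_width) + 1L)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins)))
  structure(list(counts = counts, bin_width = bin_width, t0 = span[1],
                 bin_starts = span[1] + (seq_len(n_bins) - 1L) * bin_width),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("Binned spike counts: %d channel(s) x %d bins of %g ms (%d spikes)\n",
              nrow(x$counts), ncol(x$counts), x$bin_width * 1000, sum(x$counts)))
  invisible(x)
}

#' Read/write binned counts as CSV (bins as rows, channels as columns)
#' @param x a `binned_counts`
#' @param path file path
#' @export
write_binned_counts_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width=%.10g", x$bin_width),
               sprintf("# t0=%.10g", x$t0)), con)
  utils::write.table(t(x$counts), con, sep = ",", row.names = FALSE,
                     col.names = paste0("ch", seq_len(nrow(x$counts))))
  invisible(path)
}

#' @rdname write_binned_counts_csv
#' @export
read_binned_counts_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  val <- function(key) as.numeric(sub(sprintf("^# %s=", key), "",
                                      grep(paste0("^# ", key, "="), hdr, value = TRUE)))
  dat <- utils::read.csv(path, comment.char = "#")
  counts <- t(as.matrix(dat))
  bw <- val("bin_width"); t0 <- val("t0")
  structure(list(counts = counts, bin_width = bw, t0 = t0,
                 bin_starts = t0 + (seq_len(ncol(counts)) - 1L) * bw),
            class = "binned_counts")
}

#' Leaky integration of binned counts
#'
#' First-order exponential decay converting spike counts into a smooth
#' population-rate estimate:
#' `r_t = r_(t-1) * exp(-bin_width / tau) + c_t`, starting from zero.
#' A constant input `c` converges to the steady state
#' `c / (1 - exp(-bin_width / tau))`.
#'
#' @param counts a [bin_spike_counts()] result (or plain matrix plus
#'   `bin_width`)
#' @param tau integrator time constant, seconds (default 0.5)
#' @param bin_width used only when `counts` is a plain matrix
#' @return object of class `integrated_rates`: list with `values`
#'   (channels x bins), `tau`, `bin_width`, `normalized = FALSE`
#' @export
leaky_integrate <- function(counts, tau = 0.5, bin_width = 0.2) {
  if (tau <= 0) stop("tau must be > 0")
  if (inherits(counts, "binned_counts")) {
    m <- counts$counts
    bin_width <- counts$bin_width
  } else m <- as.matrix(counts)
  decay <- exp(-bin_width / tau)
  out <- matrix(0, nrow(m), ncol(m))
  r <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    r <- r * decay + m[, j]
    out[, j] <- r
  }
  structure(list(values = out, tau = tau, bin_width = bin_width,
                 normalized = FALSE),
            class = "integrated_rates")
}

#' Cross-channel population activity
#'
#' Sums integrated rates across channels per bin, optionally after
#' per-channel max-normalization (each channel divided by its maximum
#' over the displayed span; all-zero channels stay zero).
#'
#' @param rates an [leaky_integrate()] result
#' @param normalize normalize each channel to max 1 first? (default TRUE)
#' @return numeric vector, one value per bin
#' @export
population_sum <- function(rates, normalize = TRUE) {
  stopifnot(inherits(rates, "integrated_rates"))
  v <- rates$values
  if (!nrow(v)) stop("no channels")
  if (normalize) {
    mx <- apply(v, 1, max)
    mx[mx == 0] <- 1
    v <- v / mx
  }
  colSums(v)
}
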