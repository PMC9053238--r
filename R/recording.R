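#' Continuous multichannel recording container
#'
#' Thin container for sampled voltage: a channels x samples matrix plus
#' sampling rate, start time and units.  Used for both spike-band and LFP
#' signals.
#'
#' @param data numeric matrix, channels x samples
#' @param fs sampling rate, Hz
#' @param t0 start time, seconds (default 0)
#' @param units signal units (default "volts")
#' @return object of class `continuous_recording`
#' @export
continuous_recording <- function(data, fs, t0 = 0, units = "volts") {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0)
  structure(list(data = data, fs = fs, t0 = t0, units = units),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("Continuous recording: %d channel(s) x %d samples @ %g Hz (%.3f s), units %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$units))
  invisible(x)
}

#' @rdname continuous_recording
#' @param x a `continuous_recording`
#' @export
rec_duration <- function(x) ncol(x$data) / x$fs

#' @rdname continuous_recording
#' @export
rec_times <- function(x) x$t0 + (seq_len(ncol(x$data)) - 1L) / x$fs

#' Read/write continuous recordings as CSV
#'
#' Small-fixture interchange format: one column per channel, one row per
#' sample, with the sampling rate, start time and units recorded in
#' `#`-prefixed header lines.
#'
#' @param x a `continuous_recording`
#' @param path file path
#' @export
write_recording_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", x$fs),
               sprintf("# t0=%.10g", x$t0),
               sprintf("# units=%s", x$units)), con)
  utils::write.table(t(x$data), con, sep = ",", row.names = FALSE,
                     col.names = paste0("ch", seq_len(nrow(x$data))))
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- function(key) sub(sprintf("^# %s=", key), "", grep(paste0("^# ", key, "="), hdr, value = TRUE))
  dat <- utils::read.csv(path, comment.char = "#")
  continuous_recording(t(as.matrix(dat)), fs = as.numeric(meta("fs")),
                       t0 = as.numeric(meta("t0")), units = meta("units"))
}

# run expr with a local RNG state seeded by `seed`; global state untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# per-module sub-seed expansion from one master seed (documented scheme:
# master * 97 + fixed module offset, folded into [0, 2^31))
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647)
}
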