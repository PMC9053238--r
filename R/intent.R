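#' Session-script intent traces
#'
#' An intent trace is the ground-truth behavioural signal a synthetic
#' session is built from: a uniform time grid carrying the attempted hand
#' action (`hand_intent`, 0 = rest, 1 = maximal attempted action), the
#' attempted elbow action (`elbow_intent`, -1 = extension, +1 = flexion)
#' and a categorical cue label.  Sessions are described by a *protocol*:
#' an ordered list of `(label, duration)` epochs, emulating the verbal cue
#' sequences used during recording sessions (rest / attempt to open or
#' close the hand / wrist extension / squeeze).
#'
#' @param protocol list of epochs, each a list or vector with elements
#'   `label` (one of `r paste(INTENT_LABELS, collapse = ", ")`) and
#'   `duration` in seconds.  A two-column data.frame with columns
#'   `label`, `duration` is also accepted.
#' @param seed integer seed (mandatory; generators keep no global state).
#'   The trace itself is deterministic given the protocol; the seed is
#'   recorded so downstream stochastic generators can derive theirs.
#' @param step grid step in seconds (default 0.02, i.e. 20 ms; must be
#'   <= 0.05).
#' @return object of class `intent_trace`: list with `times`,
#'   `hand_intent`, `elbow_intent`, `label` (character), `step`, `seed`.
#' @export
make_intent_trace <- function(protocol, seed, step = 0.02) {
  if (missing(seed)) stop("seed is mandatory")
  protocol <- as_protocol(protocol)
  if (nrow(protocol) == 0L) stop("empty session script")
  if (any(protocol$duration <= 0)) stop("epoch durations must be > 0")
  if (step > 0.05) stop("grid step must be <= 50 ms")

  total <- sum(protocol$duration)
  n <- round(total / step)
  times <- (seq_len(n) - 1L) * step
  edges <- cumsum(protocol$duration)
  # epoch index of each sample: first epoch whose right edge exceeds t
  idx <- findInterval(times, c(0, edges), rightmost.closed = FALSE)
  idx[idx > nrow(protocol)] <- nrow(protocol)
  label <- protocol$label[idx]
  structure(list(
    times = times,
    hand_intent = unname(HAND_INTENT_OF[label]),
    elbow_intent = unname(ELBOW_INTENT_OF[label]),
    label = label,
    step = step,
    seed = as.integer(seed)
  ), class = "intent_trace")
}

#' @export
print.intent_trace <- function(x, ...) {
  cat("Intent trace:", length(x$times), "samples,",
      format(length(x$times) * x$step), "s at", x$step * 1000, "ms step\n")
  cat("  labels:", paste(rle(x$label)$values, collapse = " -> "), "\n")
  invisible(x)
}

INTENT_LABELS <- c("rest", "attempt_open", "attempt_close", "wrist_ext", "squeeze")

# attempted-action magnitudes by cue; hand_intent in [0,1]
HAND_INTENT_OF <- c(rest = 0, attempt_open = 1, attempt_close = 1,
                    wrist_ext = 0.6, squeeze = 1)
ELBOW_INTENT_OF <- c(rest = 0, attempt_open = 0, attempt_close = 0,
                     wrist_ext = 0, squeeze = 0)

as_protocol <- function(protocol) {
  if (is.data.frame(protocol)) {
    stopifnot(all(c("label", "duration") %in% names(protocol)))
    out <- protocol[, c("label", "duration")]
  } else if (is.list(protocol)) {
    if (length(protocol) == 0L) stop("empty session script")
    out <- data.frame(
      label = vapply(protocol, function(e) as.character(e[[1]]), ""),
      duration = vapply(protocol, function(e) as.numeric(e[[2]]), 0)
    )
  } else stop("protocol must be a list of (label, duration) epochs")
  bad <- setdiff(out$label, INTENT_LABELS)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  out
}

#' Alternating movement/rest protocol helper
#'
#' @param move_label movement cue label
#' @param move_s,rest_s epoch durations in seconds
#' @param n_cycles number of (movement, rest) pairs
#' @param lead_rest_s optional leading rest epoch (0 to omit)
#' @return protocol data.frame usable by [make_intent_trace()]
#' @export
alternating_protocol <- function(move_label = "attempt_close", move_s = 5,
                                 rest_s = 5, n_cycles = 6, lead_rest_s = 0) {
  blocks <- do.call(rbind, lapply(seq_len(n_cycles), function(i) {
    data.frame(label = c(move_label, "rest"), duration = c(move_s, rest_s))
  }))
  if (lead_rest_s > 0)
    blocks <- rbind(data.frame(label = "rest", duration = lead_rest_s), blocks)
  blocks
}

#' Cursor training-block target trajectory
#'
#' The calibration cursor moves slowly from the top of the screen to the
#' bottom and back, taking `half_period` seconds each way; a one-minute
#' block with 5-s half-period therefore contains six full
#' top-bottom-top cycles.  The trajectory is a triangle wave on the
#' normalized screen coordinate (1 = top, 0 = bottom) starting at the top.
#'
#' @param duration block length in seconds (default 60)
#' @param half_period seconds for one top-to-bottom sweep (default 5)
#' @param step sample step in seconds (default 0.02)
#' @return list with `times` and `target_y` in \[0, 1\]
#' @export
make_cursor_training_block <- function(duration = 60, half_period = 5,
                                       step = 0.02) {
  stopifnot(duration > 0, half_period > 0, step > 0)
  times <- seq(0, duration, by = step)
  phase <- (times / half_period) %% 2
  target_y <- ifelse(phase <= 1, 1 - phase, phase - 1)
  list(times = times, target_y = target_y,
       duration = duration, half_period = half_period)
}
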