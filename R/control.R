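#' Motion commands
#'
#' The discrete hand-motor commands shared by every control pathway:
#' `"open"` (extension), `"hold"`, `"close"` (flexion).
#'
#' @name motion-commands
#' @export
CMD_OPEN <- "open"
#' @rdname motion-commands
#' @export
CMD_HOLD <- "hold"
#' @rdname motion-commands
#' @export
CMD_CLOSE <- "close"

#' Single-threshold discretization of decoder output
#'
#' Decision rule 1 of the decoder-output discretization block: the
#' continuous filter output `x_t` (a screen position) maps to extension
#' (open) when `x_t < AT` and flexion (close) when `x_t >= AT`.
#'
#' @param x decoder output(s)
#' @param at position threshold AT
#' @return motion command(s): `"open"` or `"close"`
#' @export
discretize_single_threshold <- function(x, at) {
  ifelse(x < at, CMD_OPEN, CMD_CLOSE)
}

#' Double-threshold discretization of decoder output
#'
#' Decision rule 2, adding a hold zone between a lower threshold `AT1`
#' and a higher threshold `AT2`: extension when `x < AT1`, hold when
#' `AT1 <= x < AT2`, flexion when `x >= AT2`.
#'
#' @param x decoder output(s)
#' @param at1,at2 lower and higher position thresholds (`at1 < at2`)
#' @return motion command(s)
#' @export
discretize_double_threshold <- function(x, at1, at2) {
  if (at1 >= at2) stop("at1 must be < at2")
  ifelse(x < at1, CMD_OPEN, ifelse(x < at2, CMD_HOLD, CMD_CLOSE))
}

#' Myoelectric DUAL-mode hand command
#'
#' The two-threshold myoelectric rule using both forearm channels: the
#' hand opens when the flexor envelope is below its threshold while the
#' extensor envelope is above its threshold; it closes in the mirror
#' case; every other combination (including co-contraction and exact
#' threshold equality) holds.  The hold clause is the complement of the
#' open/close clauses.
#'
#' @param flexors,extensors rectified-RMS envelopes (>= 0)
#' @param flex_th,ext_th manually set thresholds (> 0)
#' @return motion command(s)
#' @export
emg_dual_mode <- function(flexors, extensors, flex_th, ext_th) {
  stopifnot(flex_th > 0, ext_th > 0)
  ifelse(flexors < flex_th & extensors > ext_th, CMD_OPEN,
         ifelse(flexors > flex_th & extensors < ext_th, CMD_CLOSE, CMD_HOLD))
}

#' Myoelectric OPEN-mode hand command
#'
#' Single-threshold rule on the extensors: the hand opens while the
#' extensor envelope exceeds its threshold and closes otherwise (the
#' exact-threshold boundary falls to the default, closed, branch).
#'
#' @param extensors rectified-RMS envelope (>= 0)
#' @param ext_th extension threshold (> 0)
#' @return motion command(s)
#' @export
emg_open_mode <- function(extensors, ext_th) {
  stopifnot(ext_th > 0)
  ifelse(extensors > ext_th, CMD_OPEN, CMD_CLOSE)
}

#' Myoelectric CLOSE-mode hand command
#'
#' Single-threshold rule on the flexors: the hand closes while the
#' flexor envelope exceeds its threshold and opens otherwise (boundary
#' to the default, open, branch).  This is the configuration used for a
#' participant with no voluntary wrist/finger extension: the hand rests
#' open and is closed by flexor activity.
#'
#' @param flexors rectified-RMS envelope (>= 0)
#' @param flex_th flexion threshold (> 0)
#' @return motion command(s)
#' @export
emg_close_mode <- function(flexors, flex_th) {
  stopifnot(flex_th > 0)
  ifelse(flexors > flex_th, CMD_CLOSE, CMD_OPEN)
}

#' Simulated orthosis hand-motor step
#'
#' First-order plant: the aperture (0 = fully closed, 1 = fully open)
#' moves toward 1 under `"open"`, toward 0 under `"close"`, and stays
#' put under `"hold"`, at `motor_rate` aperture units per second,
#' clamped to \[0, 1\].
#'
#' @param aperture current aperture in \[0, 1\]
#' @param cmd a motion command
#' @param dt step length, seconds (> 0)
#' @param motor_rate aperture units per second (default 2, i.e. full
#'   travel in 0.5 s)
#' @return new aperture
#' @export
orthosis_step <- function(aperture, cmd, dt, motor_rate = 2) {
  if (dt <= 0) stop("dt must be > 0")
  dir <- switch(cmd, open = 1, close = -1, hold = 0,
                stop("unknown command: ", cmd))
  min(1, max(0, aperture + dir * motor_rate * dt))
}
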