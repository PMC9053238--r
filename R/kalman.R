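#' Fit a position-velocity Kalman filter decoder
#'
#' Classic kinematic-state neural decoder: the hidden state is
#' `(position, velocity)` per controlled dimension, evolving as
#' `s_(t+1) = A s_t + w` with `w ~ N(0, W)`, observed through neural
#' features `z_t = H s_t + q` with `q ~ N(0, Q)`.  `A` and `W` are fit
#' by least squares on the training state transitions; `H` and `Q` by
#' least squares of the observations on the states.  Velocity training
#' targets are typically finite differences of the cursor trajectory.
#'
#' @param states n x d matrix of training states (columns e.g. position,
#'   velocity)
#' @param observations n x p matrix of simultaneous neural features
#' @return object of class `kalman_model` with `A`, `W`, `H`, `Q`
#' @export
fit_kalman <- function(states, observations) {
  S <- as.matrix(states)
  Z <- as.matrix(observations)
  stopifnot(nrow(S) == nrow(Z), nrow(S) >= ncol(S) + 1)
  S0 <- S[-nrow(S), , drop = FALSE]
  S1 <- S[-1, , drop = FALSE]
  A <- t(solve(crossprod(S0), crossprod(S0, S1)))
  rw <- S1 - S0 %*% t(A)
  W <- crossprod(rw) / (nrow(rw) - 1)
  H <- t(solve(crossprod(S), crossprod(S, Z)))
  rq <- Z - S %*% t(H)
  Q <- crossprod(rq) / (nrow(rq) - 1)
  structure(list(A = A, W = sym(W), H = H, Q = sym(Q)),
            class = "kalman_model")
}

sym <- function(M) (M + t(M)) / 2

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("Kalman decoder: %d-dim state, %d-dim observation\n",
              nrow(x$A), nrow(x$H)))
  invisible(x)
}

#' One predict/update step of the Kalman recursion
#'
#' Standard recursion: predict `m- = A m`, `P- = A P A' + W`; update with
#' gain `K = P- H' (H P- H' + Q)^-1`, posterior mean
#' `m- + K (z - H m-)` and covariance `(I - K H) P-`.  With `Q -> Inf`
#' the observation is ignored (posterior = prior); with `W = 0` the
#' state follows `A` deterministically.
#'
#' @param model a [fit_kalman()] result, or a list with `A`, `W`, `H`, `Q`
#' @param mean prior state mean (vector)
#' @param cov prior state covariance (must be symmetric PSD)
#' @param observation observed feature vector `z`
#' @return list with posterior `mean` and `cov` (and the predicted
#'   `mean_pred`, `cov_pred`)
#' @export
kalman_step <- function(model, mean, cov, observation) {
  A <- as.matrix(model$A); W <- as.matrix(model$W)
  H <- as.matrix(model$H); Q <- as.matrix(model$Q)
  cov <- as.matrix(cov)
  check_psd(cov, "prior covariance")
  check_psd(W, "process covariance W")
  check_psd(Q, "observation covariance Q")
  m_pred <- drop(A %*% mean)
  P_pred <- sym(A %*% cov %*% t(A) + W)
  S <- sym(H %*% P_pred %*% t(H) + Q)
  if (all(is.infinite(diag(Q)))) {
    return(list(mean = m_pred, cov = P_pred,
                mean_pred = m_pred, cov_pred = P_pred))
  }
  K <- P_pred %*% t(H) %*% solve(S)
  m_post <- m_pred + drop(K %*% (observation - H %*% m_pred))
  P_post <- sym((diag(nrow(P_pred)) - K %*% H) %*% P_pred)
  list(mean = m_post, cov = P_post, mean_pred = m_pred, cov_pred = P_pred)
}

check_psd <- function(M, what) {
  M <- as.matrix(M)
  if (any(is.infinite(M))) return(invisible(TRUE))  # Inf = uninformative
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop(what, " must be symmetric")
  ev <- eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop(what, " must be positive semi-definite")
  invisible(TRUE)
}

#' Run a Kalman decoder over an observation sequence
#'
#' @param model a [fit_kalman()] result
#' @param observations n x p matrix, one row per time step
#' @param mean0,cov0 initial state (defaults: zero mean, identity cov)
#' @return matrix of posterior state means, one row per step
#' @export
kalman_filter_run <- function(model, observations,
                              mean0 = rep(0, nrow(model$A)),
                              cov0 = diag(nrow(model$A))) {
  Z <- as.matrix(observations)
  out <- matrix(0, nrow(Z), nrow(model$A))
  m <- mean0; P <- cov0
  for (t in seq_len(nrow(Z))) {
    st <- kalman_step(model, m, P, Z[t, ])
    m <- st$mean; P <- st$cov
    out[t, ] <- m
  }
  out
}
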