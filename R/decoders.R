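#' Assemble a lagged design matrix from binned features
#'
#' Row `t` of the design contains the feature vector at bins
#' `t, t-1, ..., t-L` (channel-major within each lag); rows with
#' incomplete history are dropped and the alignment recorded, so the
#' target can be matched bin for bin.
#'
#' @param features channels x bins numeric matrix (spike counts or band
#'   powers), or a [bin_spike_counts()] result
#' @param target numeric vector, one value per bin (optional)
#' @param lags integer bin offsets, e.g. `0:4` for taps at 0-800 ms with
#'   200-ms bins (default `0:4`)
#' @return list with `X` (rows x (channels*|lags|)), `y` (aligned
#'   target, or NULL), `rows` (bin indices kept), `lags`, `n_channels`
#' @export
assemble_feature_matrix <- function(features, target = NULL, lags = 0:4) {
  if (inherits(features, "binned_counts")) features <- features$counts
  features <- as.matrix(features)
  if (!length(lags)) stop("lags must be non-empty")
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0)) stop("lags must be >= 0")
  n_ch <- nrow(features)
  n_bin <- ncol(features)
  max_lag <- max(lags)
  if (n_bin <= max_lag) stop("not enough bins to cover max lag")
  rows <- (max_lag + 1L):n_bin
  X <- do.call(cbind, lapply(lags, function(L) t(features[, rows - L, drop = FALSE])))
  colnames(X) <- as.vector(outer(paste0("ch", seq_len(n_ch)),
                                 paste0("_lag", lags), paste0))
  y <- if (!is.null(target)) {
    stopifnot(length(target) == n_bin)
    target[rows]
  } else NULL
  list(X = X, y = y, rows = rows, lags = lags, n_channels = n_ch)
}

#' Fit a ridge linear filter decoder
#'
#' The continuous decoder used for cursor and orthosis control: a
#' weighted linear combination of (lagged) neural features predicting a
#' one-dimensional kinematic output.  Features are standardized (the
#' centering/scaling is stored in the model and re-applied at prediction
#' time) and the coefficients minimize
#' `||y - b0 - Xw||^2 + ridge * ||w||^2` with the intercept unpenalized.
#'
#' @param design numeric design matrix (rows = time bins), e.g. the `X`
#'   from [assemble_feature_matrix()]
#' @param target numeric response, one per row
#' @param ridge ridge penalty; the default `NULL` uses
#'   `1e-3 * mean(feature variance)`, and `ridge = 0` requests ordinary
#'   least squares (error on singular designs)
#' @param lags,n_channels optional metadata stored for streaming
#'   prediction
#' @return object of class `linear_filter` with elements `weights`,
#'   `intercept`, `center`, `scale`, `ridge`, `lags`, `n_channels`,
#'   `r_squared`, `fitted`
#' @export
fit_linear_filter <- function(design, target, ridge = NULL,
                              lags = NULL, n_channels = NULL) {
  X <- as.matrix(design)
  y <- as.numeric(target)
  stopifnot(nrow(X) == length(y))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (is.null(ridge)) ridge <- 1e-3 * mean(apply(Xs, 2, stats::var))
  if (ridge < 0) stop("ridge must be >= 0")
  ym <- mean(y)
  yc <- y - ym
  G <- crossprod(Xs) + diag(ridge, ncol(Xs))
  w <- tryCatch(solve(G, crossprod(Xs, yc)),
                error = function(e) stop("singular design; use ridge > 0"))
  if (ridge == 0 && rcond_est(G) < 1e-12) stop("singular design; use ridge > 0")
  fitted <- drop(Xs %*% w) + ym
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - ym)^2)
  structure(list(weights = drop(w), intercept = ym, center = ctr, scale = scl,
                 ridge = ridge, lags = lags, n_channels = n_channels,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 fitted = fitted),
            class = "linear_filter")
}

rcond_est <- function(A) {
  s <- svd(A, nu = 0, nv = 0)$d
  if (max(s) == 0) 0 else min(s) / max(s)
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf("Linear filter decoder: %d weights, ridge = %.3g, training R^2 = %.3f\n",
              length(x$weights), x$ridge, x$r_squared))
  invisible(x)
}

#' @export
coef.linear_filter <- function(object, ...) {
  # report on the original feature scale
  w <- object$weights / object$scale
  b0 <- object$intercept - sum(object$weights * object$center / object$scale)
  c(`(Intercept)` = b0, w)
}

#' @param object,newdata standard predict arguments; `newdata` is a
#'   design matrix with the training columns
#' @param ... unused
#' @rdname fit_linear_filter
#' @export
predict.linear_filter <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$weights)) stop("channel/lag mismatch with training design")
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  drop(Xs %*% object$weights) + object$intercept
}

#' Run a fitted linear filter over a binned feature stream
#'
#' Causal streaming prediction: assembles the lagged design from the
#' feature matrix (using the lags stored in the model) and predicts one
#' output per bin after the history warm-up.
#'
#' @param model a fitted [linear_filter][fit_linear_filter] carrying
#'   `lags` and `n_channels`
#' @param features channels x bins matrix (same channel set as training)
#' @return list with `x` (decoder output series) and `rows` (bin indices)
#' @export
predict_linear_stream <- function(model, features) {
  if (inherits(features, "binned_counts")) features <- features$counts
  if (is.null(model$lags)) stop("model carries no lag metadata")
  if (nrow(features) != model$n_channels)
    stop("channel mismatch: model trained on ", model$n_channels, " channels")
  asm <- assemble_feature_matrix(features, lags = model$lags)
  list(x = predict(model, asm$X), rows = asm$rows)
}
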