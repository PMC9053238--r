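#' Linear discriminant analysis classifier
#'
#' Discrete decoder over movement classes (e.g. extension vs flexion):
#' Gaussian classes with per-class means, a pooled covariance and class
#' priors estimated from the training frequencies.  Prediction picks the
#' class maximizing the linear discriminant
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`, breaking exact ties
#' deterministically in favour of the first class (training order).
#'
#' @param features n x p numeric matrix
#' @param labels factor or character vector of class labels (>= 2
#'   classes, each with >= 2 samples)
#' @param shrinkage ridge added to the pooled covariance diagonal as a
#'   fraction of its mean diagonal (default 0); use > 0 when the pooled
#'   covariance is singular
#' @return object of class `lda_model` with `means`, `cov`, `priors`,
#'   `classes`
#' @export
fit_lda <- function(features, labels, shrinkage = 0) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need >= 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) stop("each class needs >= 2 samples")
  means <- t(vapply(classes, function(k) colMeans(X[labels == k, , drop = FALSE]),
                    numeric(ncol(X))))
  Sp <- matrix(0, ncol(X), ncol(X))
  for (k in classes) {
    Xk <- X[labels == k, , drop = FALSE]
    Sp <- Sp + crossprod(sweep(Xk, 2, colMeans(Xk)))
  }
  Sp <- Sp / (nrow(X) - length(classes))
  if (shrinkage > 0) Sp <- Sp + diag(shrinkage * mean(diag(Sp)), ncol(X))
  Sinv <- tryCatch(solve(Sp), error = function(e)
    stop("singular pooled covariance; set shrinkage > 0"))
  structure(list(means = means, cov = Sp, cov_inv = Sinv,
                 priors = as.numeric(counts) / nrow(X), classes = classes),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("LDA classifier:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "), priors",
      paste(round(x$priors, 3), collapse = "/"), "\n")
  invisible(x)
}

#' @param model a fitted `lda_model`
#' @param features matrix (or vector) of points to classify
#' @rdname fit_lda
#' @export
predict_lda <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  d <- vapply(seq_along(model$classes), function(k) {
    mu <- model$means[k, ]
    drop(X %*% model$cov_inv %*% mu) -
      0.5 * drop(t(mu) %*% model$cov_inv %*% mu) +
      log(model$priors[k])
  }, numeric(nrow(X)))
  d <- matrix(d, nrow = nrow(X))
  # which.max returns the first maximum: ties go to the first class
  model$classes[apply(d, 1, which.max)]
}
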