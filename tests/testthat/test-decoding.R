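test_that("lagged design assembly trims incomplete history", {
  f <- matrix(seq_len(30), nrow = 3)  # 3 channels x 10 bins
  a0 <- assemble_feature_matrix(f, lags = 0)
  expect_equal(nrow(a0$X), 10)
  a4 <- assemble_feature_matrix(f, target = 1:10, lags = 0:4)
  expect_equal(nrow(a4$X), 6)
  expect_equal(ncol(a4$X), 15)
  expect_equal(a4$y, 5:10)
  # row t carries features at t, t-1, ..., t-4 (channel-major per lag)
  expect_equal(unname(a4$X[1, 1:3]), f[, 5])
  expect_equal(unname(a4$X[1, 13:15]), f[, 1])
  expect_error(assemble_feature_matrix(f, lags = integer(0)), "lags")
  expect_error(assemble_feature_matrix(f[, 1:3], lags = 0:4), "not enough bins")
})

test_that("channel permutations do not change fitted predictions", {
  set.seed(20)
  f <- matrix(rpois(200, 5), nrow = 4)
  y <- 0.5 * f[1, ] - 0.2 * f[3, ] + rnorm(50, sd = 0.1)
  perm <- c(3, 1, 4, 2)
  a1 <- assemble_feature_matrix(f, y, lags = 0:2)
  a2 <- assemble_feature_matrix(f[perm, ], y, lags = 0:2)
  m1 <- fit_linear_filter(a1$X, a1$y, ridge = 1e-6)
  m2 <- fit_linear_filter(a2$X, a2$y, ridge = 1e-6)
  expect_equal(predict(m1, a1$X), predict(m2, a2$X), tolerance = 1e-8)
})

test_that("ordinary least squares recovers exact linear maps", {
  set.seed(21)
  X <- matrix(rnorm(200), ncol = 2)
  y <- 2 * X[, 1] - X[, 2]
  m <- fit_linear_filter(X, y, ridge = 0)
  co <- coef(m)
  expect_equal(unname(co[-1]), c(2, -1), tolerance = 1e-8)
  expect_equal(unname(co[1]), 0, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  # degenerate constant features without ridge must fail loudly
  Xc <- cbind(X[, 1], X[, 1])
  expect_error(fit_linear_filter(Xc, y, ridge = 0), "singular")
})

test_that("ridge shrinks null effects toward zero", {
  set.seed(22)
  n <- 10000
  X <- matrix(rnorm(n * 3), ncol = 3)
  y <- rnorm(n)
  m <- fit_linear_filter(X, y, ridge = 1)
  expect_true(all(abs(coef(m)[-1]) < 0.1))
})

test_that("the ridge solution matches the normal-equations oracle", {
  set.seed(23)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 5), ncol = 5)
    y <- rnorm(20)
    lam <- runif(1, 0.01, 2)
    m <- fit_linear_filter(X, y, ridge = lam)
    # brute-force: standardize, solve (X'X + lam I) w = X'(y - ybar)
    Xs <- scale(X)
    w <- solve(crossprod(Xs) + diag(lam, 5), crossprod(Xs, y - mean(y)))
    expect_equal(unname(m$weights), unname(drop(w)), tolerance = 1e-8)
  }
})

test_that("prediction is consistent, causal and linear in the weights", {
  set.seed(24)
  f <- matrix(rpois(300, 4), nrow = 5)
  y <- colSums(f * c(0.4, -0.1, 0, 0.2, 0)) + rnorm(60, sd = 0.2)
  a <- assemble_feature_matrix(f, y, lags = 0:2)
  m <- fit_linear_filter(a$X, a$y, lags = 0:2, n_channels = 5)
  expect_equal(predict(m, a$X), m$fitted)
  st <- predict_linear_stream(m, f)
  expect_equal(st$x, m$fitted)            # same design, same predictions
  expect_equal(st$rows, 3:60)
  m2 <- m
  m2$weights <- 2 * m$weights
  expect_equal(predict(m2, a$X) - m$intercept,
               2 * (predict(m, a$X) - m$intercept), tolerance = 1e-10)
  expect_error(predict_linear_stream(m, f[1:3, ]), "channel mismatch")
  # zero features with zero intercept decode to zero
  m0 <- m
  m0$weights[] <- 0
  m0$intercept <- 0
  expect_true(all(predict(m0, a$X) == 0))
})

test_that("held-out cursor tracking exceeds 0.7 on generator sessions", {
  p <- synthetic_participant(seed = 30)
  cal <- two_stage_calibration(p, seed = 31)
  expect_gt(cal$r_squared["stage2"], 0.7)
  held <- closed_loop_tracking_corr(cal$model, p, seed = 32)
  expect_gt(held, 0.7)
})

test_that("two-stage calibration is deterministic and feedback-aware", {
  p <- synthetic_participant(seed = 30)
  c1 <- two_stage_calibration(p, seed = 33)
  c2 <- two_stage_calibration(p, seed = 33)
  expect_identical(c1$model$weights, c2$model$weights)
  # no feedback sensitivity: the two stages land on equivalent decoders
  a <- assemble_feature_matrix(c1$counts1, lags = 0:4)
  expect_gt(cor(predict(c1$stage1, a$X), predict(c1$model, a$X)), 0.9)
  # feedback-perturbed participant: stage 2 tracks the closed-loop
  # generator at least as well as stage 1 (fixed-seed regression)
  pf <- synthetic_participant(feedback_gain = 1, seed = 5)
  cf <- two_stage_calibration(pf, seed = 7)
  s1 <- closed_loop_tracking_corr(cf$stage1, pf, seed = 99)
  s2 <- closed_loop_tracking_corr(cf$model, pf, seed = 99)
  expect_gte(s2, s1)
})
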