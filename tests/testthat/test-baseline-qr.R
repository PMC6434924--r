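test_that("check loss: values and positivity", {
  expect_equal(check_loss(0, 0.3), 0)
  expect_equal(check_loss(2, 0.5), 1)
  expect_equal(check_loss(-1, 0.95), 0.05)
  set.seed(1)
  u <- rnorm(50)
  for (tau in c(0.1, 0.5, 0.9)) {
    v <- check_loss(u, tau)
    expect_true(all(v >= 0))
    expect_identical(v == 0, u == 0)
  }
  expect_error(check_loss(1, 1), class = "qr_invalid_input")
})

test_that("intercept-only fits are exact sample quantiles of the LP", {
  s5 <- regression_sample(1:5)
  f <- fit_linear_qr(s5, 0.5)
  expect_equal(f$beta, 3)
  expect_equal(f$objective, 3)   # 0.5 * (2 + 1 + 0 + 1 + 2)
  s10 <- regression_sample(as.numeric(1:10))
  f9 <- fit_linear_qr(s10, 0.9)
  expect_equal(f9$beta, 9)
  for (c in 1:10)
    expect_lte(f9$objective, bf_objective(1:10, NULL, c, 0.9) + 1e-12)
})

test_that("one-covariate fit: perfect line, oracle equivalence, equivariance", {
  s <- regression_sample(c(3, 5, 7), c(1, 2, 3))
  f <- fit_linear_qr(s, 0.3)
  expect_equal(f$beta, c(1, 2), tolerance = 1e-12)
  expect_equal(f$objective, 0)
  expect_equal(f$n_interpolated, 3L)

  # brute-force enumeration over all two-point lines, random instances
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    tau <- sample(c(0.1, 0.5, 0.9, 0.95), 1)
    fit <- fit_linear_qr(regression_sample(y, x), tau)
    oracle <- bf_pairs_min(x, y, tau)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-8)
    expect_equal(bf_objective(y, x, fit$beta, tau), fit$objective,
                 tolerance = 1e-8)
  }

  # shift and scale equivariance
  set.seed(22)
  x <- runif(40); y <- 1 + 2 * x + rt(40, df = 3)
  f0 <- fit_linear_qr(regression_sample(y, x), 0.75)
  fs <- fit_linear_qr(regression_sample(y + 5, x), 0.75)
  expect_equal(fs$beta[1], f0$beta[1] + 5, tolerance = 1e-8)
  expect_equal(fs$beta[2], f0$beta[2], tolerance = 1e-8)
  fm <- fit_linear_qr(regression_sample(3 * y, x), 0.75)
  expect_equal(fm$beta, 3 * f0$beta, tolerance = 1e-8)
})

test_that("objective never exceeds the truth's on simulated linear data", {
  for (sd in 1:20) {
    set.seed(sd)
    x <- runif(30, 0, 2)
    beta_true <- c(1, 2)
    y <- beta_true[1] + beta_true[2] * x + rnorm(30)
    tau <- 0.9
    fit <- fit_linear_qr(regression_sample(y, x), tau)
    qtrue <- beta_true + c(qnorm(tau), 0)  # true conditional quantile line
    expect_lte(fit$objective, bf_objective(y, x, qtrue, tau) + 1e-10)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_linear_qr(regression_sample(rnorm(6), rep(2, 6)), 0.5),
               class = "qr_degenerate_design")
})

test_that("two-covariate fit (MM + polish) tracks the check-loss optimum", {
  set.seed(31)
  n <- 40
  X <- cbind(runif(n), rnorm(n))
  y <- 1 + X %*% c(2, -1) + rnorm(n)
  for (tau in c(0.25, 0.5, 0.9)) {
    fit <- fit_linear_qr(regression_sample(as.numeric(y), X), tau)
    # optimum interpolates p = 3 points and beats random perturbations
    expect_gte(fit$n_interpolated, 1L)
    o <- fit$objective
    for (k in 1:20) {
      b <- fit$beta + rnorm(3, sd = 0.05)
      expect_lte(o, bf_objective(as.numeric(y), X, b, tau) + 1e-9)
    }
  }
})

test_that("linear prediction is exact affine evaluation", {
  s <- regression_sample(c(3, 5, 7), c(1, 2, 3))
  fit <- fit_linear_qr(s, 0.5)        # beta = (1, 2)
  cv <- predict_linear_qr(fit, c(0, 1, 2, 3))
  expect_equal(cv$q, c(1, 3, 5, 7))
  expect_s3_class(cv, "quantile_curve")
  expect_identical(cv$method, "linear")
  expect_error(predict_linear_qr(fit, matrix(1:6, ncol = 2)),
               class = "qr_invalid_input")
})

test_that("local-linear fit: perfect line, wide-bandwidth limit, tie-break", {
  x <- c(0.5, 1, 1.8, 2.6, 3)
  s <- regression_sample(2 * x + 1, x)
  for (tau in c(0.2, 0.8)) {
    lf <- fit_lpqr(s, tau, x0 = 1.4, h = 0.7)
    expect_equal(lf$a0, 2 * 1.4 + 1, tolerance = 1e-10)
    expect_equal(lf$a1, 2, tolerance = 1e-10)
    expect_equal(lf$objective, 0, tolerance = 1e-12)
  }
  set.seed(41)
  x <- runif(25); y <- rnorm(25) + x
  s <- regression_sample(y, x)
  glob <- fit_linear_qr(s, 0.7)
  loc <- fit_lpqr(s, 0.7, x0 = 0.5, h = 1e6)
  expect_equal(loc$a0 + loc$a1 * (0.9 - 0.5),
               glob$beta[1] + glob$beta[2] * 0.9, tolerance = 1e-4)
  # local constant fit with symmetric weights: tie broken toward the
  # smaller candidate
  s2 <- regression_sample(c(0, 10), c(-1, 1))
  lf0 <- fit_lpqr(s2, 0.5, x0 = 0, h = 1, intercept_only = TRUE)
  expect_equal(lf0$a0, 0)
  expect_equal(lf0$a1, 0)
  expect_error(fit_lpqr(regression_sample(c(1, 2), c(0, 40)), 0.5,
                        x0 = 0, h = 0.5),
               class = "qr_insufficient_local_data")
})

test_that("lpqr curve agrees with pointwise fits inside the data range", {
  set.seed(51)
  s <- gumbel_fixture(60, seed = 51)
  xg <- c(0.4, 1, 1.7)
  cv <- lpqr_curve(s, 0.9, xg, h = 0.6)
  for (k in seq_along(xg)) {
    lf <- fit_lpqr(s, 0.9, xg[k], h = 0.6)
    expect_equal(cv$q[k], lf$a0, tolerance = 1e-10)
  }
  # outside the covariate range the curve clamps to the boundary fit
  far <- lpqr_curve(s, 0.9, c(max(s$X) + 2, max(s$X) + 5), h = 0.6)
  expect_equal(far$q[1], far$q[2], tolerance = 1e-12)
  expect_equal(far$provenance$n_clamped, 2L)
})
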