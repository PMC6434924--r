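test_that("regression_sample validates shapes and finiteness", {
  s <- regression_sample(rnorm(10), matrix(rnorm(20), ncol = 2))
  expect_equal(s$n, 10L); expect_equal(s$d, 2L)
  expect_error(regression_sample(c(1, NA, 3)), class = "qr_invalid_input")
  expect_error(regression_sample(1:4, matrix(1:6, ncol = 2)),
               class = "qr_invalid_input")
})

test_that("conditional density: point-mass reduction and unit integral", {
  # single observation, product kernel, fixed bandwidths: the conditional
  # is one Gaussian bump centered at y1
  s1 <- regression_sample(2, 0.5)
  g <- seq(-3, 7, length.out = 401)
  f <- conditional_density(s1, 0.5, y_grid = g, bw = c(1, 1),
                           kernel_type = "product")
  expect_equal(as.numeric(f), dnorm(g, mean = 2), tolerance = 1e-12)

  set.seed(61)
  s <- gumbel_fixture(60, seed = 61)
  f2 <- conditional_density(s, 1)
  g2 <- attr(f2, "y_grid")
  expect_true(all(f2 >= 0))
  expect_equal(bf_trapz(g2, as.numeric(f2)), 1, tolerance = 0.01)
})

test_that("conditional density approaches the marginal when y is independent of x", {
  set.seed(62)
  n <- 500
  y <- rnorm(n); x <- runif(n)          # pure noise covariate
  s <- regression_sample(y, x)
  hy <- per_dimension_bandwidth(y)
  g <- seq(-4, 4, length.out = 201)
  f <- conditional_density(s, 0.5, y_grid = g, kernel_type = "product")
  expect_lt(max(abs(as.numeric(f) - bf_kde1(y, g, hy))), 0.05)
})

test_that("conditional CDF: normalization, tail mass, exponential sup-norm", {
  set.seed(63)
  s <- gumbel_fixture(80, seed = 63)
  Fv <- conditional_cdf(s, 0.8)
  expect_equal(as.numeric(Fv)[length(Fv)], 1)
  expect_true(all(diff(as.numeric(Fv)) >= -1e-12))
  raw <- as.numeric(Fv) * attr(Fv, "raw_total")
  expect_lt(raw[1], 0.005)
  expect_gt(attr(Fv, "coverage"), 0.95)

  # y ~ Exp(1) with an independent covariate: compare to the true CDF
  # (grid extends below 0 to capture the kernel mass smeared left of the
  # support boundary)
  set.seed(64)
  y <- rexp(200); x <- runif(200)
  s2 <- regression_sample(y, x)
  g <- seq(-3, 12, length.out = 600)
  F2 <- conditional_cdf(s2, 0.5, y_grid = g)
  err <- abs(as.numeric(F2) - pexp(g))
  # an uncorrected Gaussian kernel smears ~0.1-0.15 of mass across the
  # support boundary at 0; away from it the estimate is accurate
  expect_lt(max(err[g >= 0.5]), 0.1)
  expect_lt(max(err), 0.2)
})

test_that("local quantile: node exactness, monotonicity in tau", {
  set.seed(65)
  s <- gumbel_fixture(50, seed = 65)
  Fv <- conditional_cdf(s, s$X[3, ])
  g <- attr(Fv, "y_grid")
  k <- which(as.numeric(Fv) > 0.4 & as.numeric(Fv) < 0.6)[1]
  tau_star <- as.numeric(Fv)[k]
  expect_equal(local_quantile(s, 3, tau_star), g[k], tolerance = 1e-10)
  taus <- c(0.05, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99)
  for (i in c(1, 10, 25)) {
    xi <- vapply(taus, function(t) local_quantile(s, i, t), numeric(1))
    expect_true(all(diff(xi) >= 0))
  }
  expect_error(local_quantile(s, 1, 1.2), class = "qr_invalid_input")
  expect_error(local_quantile(s, 0, 0.5), class = "qr_invalid_input")
})

test_that("local quantiles track the closed-form truth on simulated pairs", {
  s <- gumbel_fixture(300, seed = 66)
  lqs <- local_quantile_set(s, 0.95)
  expect_length(lqs$xi, 300)
  truth <- gumbel_conditional_quantile(0.95, s$X[, 1], gumbel_params(1))
  # kernel smoothing at n = 300 keeps the mean absolute inversion error
  # well under half a response unit (truth spans about [1.5, 3.7])
  expect_lt(mean(abs(lqs$xi - truth)), 0.5)
})

test_that("NW weights: simplex properties and hand oracle", {
  expect_equal(nw_weights(0.3, 1.2, 0.5), 1)
  expect_equal(nw_weights(0, c(-1, 1), 0.8), c(0.5, 0.5))
  x3 <- c(0, 1, 3)
  w <- nw_weights(0.5, x3, 1)
  kw <- dnorm((0.5 - x3) / 1)
  expect_equal(w, kw / sum(kw), tolerance = 1e-14)
  set.seed(67)
  X <- matrix(rnorm(60), ncol = 2)
  for (k in 1:5) {
    w <- nw_weights(rnorm(2), X, c(0.4, 0.7))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(nw_weights(1e6, c(0, 1), 0.1), class = "qr_extrapolation")
})

test_that("direct curve: convex bound, dominant weight at isolated point", {
  s <- gumbel_fixture(80, seed = 68)
  lqs <- local_quantile_set(s, 0.95)
  cv <- direct_quantile_curve(s, 0.95, x_eval = seq(0, 5, 0.1))
  expect_true(all(cv$q >= min(lqs$xi) - 1e-10))
  expect_true(all(cv$q <= max(lqs$xi) + 1e-10))

  # isolated data point dominates the average at its own location
  x <- c(seq(0, 0.5, length.out = 9), 30)
  y <- c(rnorm(9), 5)
  si <- regression_sample(y, x)
  h <- 0.3
  cvi <- direct_quantile_curve(si, 0.5, x_eval = 30, bw_smooth = h,
                               bw_density = c(1, 1), kernel_type = "product")
  lqi <- local_quantile_set(si, 0.5, bw = c(1, 1), kernel_type = "product")
  expect_equal(cvi$q, lqi$xi[10], tolerance = 1e-6)
})

test_that("direct curves never cross and nest across tau (seeded samples)", {
  for (sd in 1:10) {
    s <- gumbel_fixture(60, seed = 100 + sd)
    cvs <- direct_quantile_curve(s, c(0.9, 0.95, 0.99),
                                 x_eval = seq(0, 4, 0.1))
    expect_true(all(cvs[[1]]$q <= cvs[[2]]$q + 1e-10), info = paste("seed", sd))
    expect_true(all(cvs[[2]]$q <= cvs[[3]]$q + 1e-10), info = paste("seed", sd))
  }
})

test_that("degenerate covariate reduces to the smoothed marginal quantile", {
  set.seed(69)
  y <- rexp(40)
  s <- regression_sample(y, rep(1, 40))
  g <- seq(min(y) - 4, max(y) + 8, length.out = 2000)
  cv <- direct_quantile_curve(s, 0.9, x_eval = c(1, 1, 1),
                              bw_density = c(0.5, 0.5), bw_smooth = 0.5,
                              kernel_type = "product")
  expect_equal(cv$q[1], cv$q[2], tolerance = 1e-12)
  # oracle: invert the plain 1-d kernel CDF of y (x carries no information)
  Fm <- cumsum(bf_kde1(y, g, 0.5)) * diff(g)[1]
  Fm <- Fm / Fm[length(Fm)]
  q_marg <- g[which(Fm >= 0.9)[1]]
  expect_equal(cv$q[1], q_marg, tolerance = 0.02)
})

test_that("integrated squared error decreases with sample size", {
  p <- gumbel_params(1)
  xg <- seq(0, 4, 0.1)
  truth <- gumbel_conditional_quantile(0.95, xg, p)
  ise <- function(n, seeds) {
    vapply(seeds, function(sd) {
      s <- gumbel_fixture(n, seed = sd)
      cv <- suppressWarnings(direct_quantile_curve(s, 0.95, x_eval = xg))
      bf_trapz(xg, (cv$q - truth)^2)
    }, numeric(1))
  }
  m100 <- mean(ise(100, 1:20))
  m400 <- mean(ise(400, 1:20))
  expect_lt(m400, m100)
})

test_that("diagnose reports coverage and flags constructed crossings", {
  s <- gumbel_fixture(500, seed = 70)
  cv <- direct_quantile_curve(s, 0.95, x_eval = seq(0, 5, 0.05))
  d1 <- diagnose(cv, s)
  expect_equal(nrow(d1$crossings), 0)
  expect_gt(d1$summary$coverage, 0.90)
  expect_lt(d1$summary$coverage, 0.99)

  cvs <- direct_quantile_curve(s, c(0.9, 0.99), x_eval = seq(0, 5, 0.05))
  ok <- diagnose(cvs, s)
  expect_true(all(ok$crossings$n_violations == 0))
  swapped <- list(quantile_curve(0.9, cvs[[2]]$x_eval, cvs[[2]]$q, "direct"),
                  quantile_curve(0.99, cvs[[1]]$x_eval, cvs[[1]]$q, "direct"))
  bad <- diagnose(swapped, s)
  expect_gt(sum(bad$crossings$n_violations), 0)
})
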