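# Independent oracles used by the unit tests.  Everything here is written
# from first principles (plain sums and enumeration) so it shares no code
# path with the package internals it checks.

# brute-force check-loss objective for a given coefficient vector
bf_objective <- function(y, X, beta, tau, w = rep(1, length(y))) {
  r <- y - as.vector(cbind(1, X) %*% beta)
  sum(w * r * (tau - (r < 0)))
}

# exact minimum over intercept-only fits: candidates are the data values
bf_intercept_min <- function(y, tau, w = rep(1, length(y))) {
  losses <- vapply(y, function(c) {
    r <- y - c
    sum(w * r * (tau - (r < 0)))
  }, numeric(1))
  k <- which(losses <= min(losses) + 1e-12)
  list(beta = min(y[k]), objective = min(losses))
}

# exact minimum over all lines through two data points (d = 1); an optimal
# basic solution of the check-loss LP interpolates two observations
bf_pairs_min <- function(x, y, tau, w = rep(1, length(y))) {
  best <- Inf; bb <- c(NA, NA)
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b1 <- (y[j] - y[i]) / (x[j] - x[i])
    b0 <- y[i] - b1 * x[i]
    r <- y - b0 - b1 * x
    loss <- sum(w * r * (tau - (r < 0)))
    if (loss < best) { best <- loss; bb <- c(b0, b1) }
  }
  list(beta = bb, objective = best)
}

# plain Gaussian KDE sum (one dimension)
bf_kde1 <- function(data, at, h) {
  vapply(at, function(p) mean(exp(-0.5 * ((p - data) / h)^2)) /
           (h * sqrt(2 * pi)), numeric(1))
}

# trapezoid quadrature
bf_trapz <- function(x, f) sum(0.5 * diff(x) * (f[-1] + f[-length(f)]))

# fresh dependent sample from the bivariate exponential (alpha = 1)
gumbel_fixture <- function(n, seed, alpha = 1) {
  d <- gumbel_sample(n, gumbel_params(alpha), seed = seed)
  regression_sample(d$y, d$x, column_names = "x")
}
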