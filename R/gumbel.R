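#' Parameters of Gumbel's second kind of bivariate exponential distribution
#'
#' The family \eqn{F(x, y) = (1 - e^{-x})(1 - e^{-y})(1 + \alpha
#' e^{-(x+y)})} on the nonnegative quadrant, with unit-exponential
#' marginals and dependence parameter `alpha`.  Density nonnegativity
#' requires \eqn{|\alpha| \le 1}; values outside `[-1, 1]` are rejected.
#'
#' @param alpha dependence parameter in `[-1, 1]` (default 1).
#' @param seed optional integer seed used by [gumbel_sample()].
#' @return object of class `gumbel_params`.
#' @export
gumbel_params <- function(alpha = 1, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      abs(alpha) > 1)
    qr_error("qr_invalid_input",
             "alpha must lie in [-1, 1] for a valid density")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      qr_error("qr_invalid_input", "seed must be a single integer")
    seed <- as.integer(seed)
  }
  structure(list(alpha = alpha, seed = seed), class = "gumbel_params")
}

as_gumbel <- function(params) {
  if (!inherits(params, "gumbel_params"))
    qr_error("qr_invalid_input", "expected gumbel_params")
  params
}

check_nonneg <- function(...) {
  args <- list(...)
  for (a in args)
    if (!is.numeric(a) || any(!is.finite(a)) || any(a < 0))
      qr_error("qr_invalid_input", "arguments must be finite and nonnegative")
  invisible(NULL)
}

#' Joint CDF of the bivariate exponential
#'
#' \eqn{F(x, y) = (1 - e^{-x})(1 - e^{-y})(1 + \alpha e^{-(x+y)})}.
#'
#' @param x,y nonnegative numeric (vectorized).
#' @param params a [gumbel_params()].
#' @return values in `[0, 1]`.
#' @export
gumbel_joint_cdf <- function(x, y, params) {
  params <- as_gumbel(params)
  check_nonneg(x, y)
  (1 - exp(-x)) * (1 - exp(-y)) * (1 + params$alpha * exp(-(x + y)))
}

#' Joint density of the bivariate exponential
#'
#' \eqn{f(x, y) = e^{-(x+y)} \{1 + \alpha (2e^{-x} - 1)(2e^{-y} - 1)\}}.
#'
#' @inheritParams gumbel_joint_cdf
#' @return nonnegative density values.
#' @export
gumbel_joint_pdf <- function(x, y, params) {
  params <- as_gumbel(params)
  check_nonneg(x, y)
  exp(-(x + y)) *
    (1 + params$alpha * (2 * exp(-x) - 1) * (2 * exp(-y) - 1))
}

#' Conditional CDF of y given x
#'
#' \eqn{F(y | x) = e^{-y} \{\alpha (2e^{-x} - 1)(1 - e^{-y}) - 1\} + 1}:
#' zero at `y = 0`, tending to one, nondecreasing in `y` for
#' \eqn{|\alpha| \le 1}.
#'
#' @param y,x nonnegative numeric (vectorized).
#' @param params a [gumbel_params()].
#' @return values in `[0, 1]`.
#' @export
gumbel_conditional_cdf <- function(y, x, params) {
  params <- as_gumbel(params)
  check_nonneg(x, y)
  ey <- exp(-y)
  ey * (params$alpha * (2 * exp(-x) - 1) * (1 - ey) - 1) + 1
}

#' True conditional quantile of y given x
#'
#' The closed-form inverse of [gumbel_conditional_cdf()] in `y`.  Writing
#' \eqn{s = \alpha(2e^{-x} - 1)}, the conditional CDF at level `tau` gives
#' the quadratic \eqn{s t^2 + (1 - s) t - (1 - \tau) = 0} in
#' \eqn{t = e^{-y}}; the root in (0, 1] is evaluated in the
#' cancellation-free form
#' \deqn{t = \frac{2 (1 - \tau)}{(1 - s) + \sqrt{(1 - s)^2 + 4 s (1 - \tau)}},}
#' which is continuous through \eqn{s = 0} (the removable singularity of
#' the textbook ratio form at \eqn{x = \ln 2} or \eqn{\alpha = 0}) and
#' stable as \eqn{\tau \to 1}.  The quantile is \eqn{-\ln t}.
#'
#' @param tau quantile level(s) in (0, 1).
#' @param x nonnegative conditioning value(s).
#' @param params a [gumbel_params()].
#' @return nonnegative quantile value(s), monotone increasing in `tau`.
#' @export
gumbel_conditional_quantile <- function(tau, x, params) {
  params <- as_gumbel(params)
  check_tau(tau)
  check_nonneg(x)
  s <- params$alpha * (2 * exp(-x) - 1)
  disc <- (1 - s)^2 + 4 * s * (1 - tau)
  t <- 2 * (1 - tau) / ((1 - s) + sqrt(disc))
  -log(t)
}

#' Exact sampler for the bivariate exponential
#'
#' Draws `x` from the unit-exponential marginal and `y` by inverse
#' transform of the conditional CDF:
#' `y = gumbel_conditional_quantile(u, x)` with `u` uniform.  The draw is
#' reproducible given a seed; the caller's RNG state is restored
#' afterwards when a seed is supplied.
#'
#' @param n number of pairs (>= 1).
#' @param params a [gumbel_params()]; its `seed` is used unless overridden.
#' @param seed optional integer overriding `params$seed`.
#' @return data frame with columns `x`, `y`.
#' @export
gumbel_sample <- function(n, params, seed = NULL) {
  params <- as_gumbel(params)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    qr_error("qr_invalid_input", "n must be a positive integer")
  n <- as.integer(n)
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  x <- stats::rexp(n)
  u <- stats::runif(n)
  y <- gumbel_conditional_quantile(u, x, params)
  data.frame(x = x, y = y)
}
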