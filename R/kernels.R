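#' Multivariate Gaussian product kernel
#'
#' Evaluates the standard d-variate Gaussian kernel
#' \eqn{K(u) = (2\pi)^{-d/2} \exp(-u^T u / 2)}, the kernel used throughout
#' the package for density estimation and Nadaraya-Watson smoothing.
#'
#' @param u numeric vector (a single point in `R^d`) or numeric matrix with
#'   one point per row.
#' @return a nonnegative scalar (vector input) or a vector with one value
#'   per row (matrix input).
#' @examples
#' gaussian_kernel(0)        # 1/sqrt(2*pi)
#' gaussian_kernel(c(0, 0))  # 1/(2*pi)
#' @export
gaussian_kernel <- function(u) {
  if (is.matrix(u)) {
    if (!all(is.finite(u))) qr_error("qr_invalid_input", "non-finite kernel argument")
    d <- ncol(u)
    return((2 * pi)^(-d / 2) * exp(-0.5 * rowSums(u * u)))
  }
  if (!is.numeric(u) || length(u) < 1L || !all(is.finite(u)))
    qr_error("qr_invalid_input", "non-finite kernel argument")
  d <- length(u)
  (2 * pi)^(-d / 2) * exp(-0.5 * sum(u * u))
}

#' Normal-reference plug-in bandwidth (scalar, d-dimensional)
#'
#' Closed-form optimal bandwidth for a Gaussian kernel when the target
#' density is taken to be standard d-variate normal:
#' \eqn{h = \{4/(d+2)\}^{1/(d+4)} n^{-1/(d+4)}}.  The rule is scale free and
#' is intended for data whitened by their sample covariance (see
#' [kde_whitened()]).
#'
#' @param n sample size (>= 2).
#' @param d dimension (>= 1).
#' @return positive scalar bandwidth.
#' @export
normal_reference_bandwidth <- function(n, d) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2)
    qr_error("qr_invalid_input", "n must be a single integer >= 2")
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 1)
    qr_error("qr_invalid_input", "d must be a single integer >= 1")
  (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
}

#' Per-dimension plug-in bandwidth
#'
#' One-dimensional normal-reference bandwidth for a single covariate
#' column, \eqn{h_j = (4/3)^{1/5} \hat\sigma_j n^{-1/5}}, with the unknown
#' curvature functional of the plug-in rule replaced by its value under a
#' normal density of scale \eqn{\hat\sigma_j}.  The scale estimate is the
#' robust \eqn{\hat\sigma_j = \min(\mathrm{sd}, \mathrm{IQR}/1.349)}.
#'
#' @param column numeric vector with at least two distinct finite values.
#' @param n sample size used in the rate; defaults to `length(column)`.
#' @return positive scalar bandwidth; scales linearly under affine
#'   rescaling of the column.
#' @export
per_dimension_bandwidth <- function(column, n = length(column)) {
  if (!is.numeric(column) || !all(is.finite(column)))
    qr_error("qr_invalid_input", "column must be finite numeric")
  sigma <- robust_scale(column)
  if (!is.finite(sigma) || sigma <= 0)
    qr_error("qr_degenerate_scale",
             "column has no spread; cannot form a bandwidth")
  (4 / 3)^(1 / 5) * sigma * n^(-1 / 5)
}

# min(sd, IQR/1.349): robust against heavy tails, exact for normal data
robust_scale <- function(x) {
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.349
  if (iqr > 0) min(s, iqr) else s
}

#' Bandwidth specification
#'
#' Bundles bandwidth values with the rule that produced them, so every
#' estimate can record its smoothing provenance.
#'
#' @param values positive numeric vector: a single scalar bandwidth or one
#'   bandwidth per dimension.
#' @param rule one of `"normal_reference_multivariate"` (scalar rule for
#'   whitened data), `"normal_reference_per_dim"` (per-column plug-in), or
#'   `"user_fixed"`.
#' @param sample_size the n that entered the rule (NA for `user_fixed`).
#' @return an object of class `bandwidth_spec`.
#' @export
bandwidth_spec <- function(values,
                           rule = c("user_fixed",
                                    "normal_reference_multivariate",
                                    "normal_reference_per_dim"),
                           sample_size = NA_integer_) {
  rule <- match.arg(rule)
  if (!is.numeric(values) || length(values) < 1L ||
      !all(is.finite(values)) || any(values <= 0))
    qr_error("qr_invalid_input", "bandwidth values must be positive and finite")
  structure(list(values = as.numeric(values), rule = rule,
                 sample_size = sample_size),
            class = "bandwidth_spec")
}

#' @export
print.bandwidth_spec <- function(x, ...) {
  cat("<bandwidth_spec> rule =", x$rule,
      " n =", x$sample_size,
      " values =", paste(signif(x$values, 5), collapse = ", "), "\n")
  invisible(x)
}

# normalize a bandwidth argument (numeric or bandwidth_spec) to a numeric
# vector of length 1 or d
bw_values <- function(bw, d) {
  v <- if (inherits(bw, "bandwidth_spec")) bw$values else bw
  if (!is.numeric(v) || !(length(v) %in% c(1L, d)) ||
      !all(is.finite(v)) || any(v <= 0))
    qr_error("qr_invalid_input",
             sprintf("bandwidth must be positive, length 1 or %d", d))
  if (length(v) == 1L) rep(v, d) else v
}

#' Per-dimension bandwidth specification for a data matrix
#'
#' Convenience constructor applying [per_dimension_bandwidth()] to every
#' column of `X`.
#'
#' @param X numeric matrix (or vector, treated as one column).
#' @param n sample size for the rate; defaults to `nrow(X)`.
#' @return a `bandwidth_spec` with rule `"normal_reference_per_dim"`.
#' @export
bw_per_dimension <- function(X, n = NROW(X)) {
  X <- as.matrix(X)
  vals <- apply(X, 2L, per_dimension_bandwidth, n = n)
  bandwidth_spec(vals, "normal_reference_per_dim", sample_size = n)
}

#' Product-kernel density estimate
#'
#' Kernel density estimate with a Gaussian product kernel,
#' \eqn{\hat g(x) = n^{-1} \sum_i \prod_j h_j^{-1} \phi\{(x_j - X_{ij})/h_j\}}.
#'
#' @param data numeric matrix (n x d) or vector (treated as one column) of
#'   observations.
#' @param points evaluation point(s): a length-d vector or an m x d matrix.
#' @param bw positive bandwidth(s): scalar, length-d vector, or a
#'   [bandwidth_spec].
#' @return nonnegative density value(s), one per evaluation point.
#' @export
kde_marginal <- function(data, points, bw) {
  data <- as.matrix(data)
  n <- nrow(data); d <- ncol(data)
  if (n < 1L) qr_error("qr_invalid_input", "empty data")
  pts <- coerce_points(points, d)
  h <- bw_values(bw, d)
  out <- numeric(nrow(pts))
  for (m in seq_len(nrow(pts))) {
    lk <- 0
    for (j in seq_len(d))
      lk <- lk + stats::dnorm((pts[m, j] - data[, j]) / h[j], log = TRUE) -
        log(h[j])
    out[m] <- mean(exp(lk))
  }
  out
}

#' Covariance-whitened kernel density estimate
#'
#' The whitened-kernel estimator
#' \deqn{\hat g(x) = \frac{(\det S)^{-1/2}}{n h^d} \sum_i
#'   k\{(x - X_i)^T S^{-1} (x - X_i) / h^2\},}
#' where S is the sample covariance of the data and
#' \eqn{k(u) = (2\pi)^{-d/2} e^{-u/2}} is the radial profile of the Gaussian
#' kernel.  The estimate is invariant under affine changes of coordinates
#' applied jointly to `data` and `points`, which makes the scale-free
#' [normal_reference_bandwidth()] an appropriate choice for `h`.
#'
#' @inheritParams kde_marginal
#' @param h positive scalar bandwidth on the whitened scale.
#' @return nonnegative density value(s), one per evaluation point.
#' @export
kde_whitened <- function(data, points, h) {
  data <- as.matrix(data)
  n <- nrow(data); d <- ncol(data)
  if (n <= d)
    qr_error("qr_degenerate_covariance",
             "need n > d observations for a nonsingular covariance")
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    qr_error("qr_invalid_input", "h must be a positive scalar")
  pts <- coerce_points(points, d)
  S <- stats::cov(data)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch))))
    qr_error("qr_degenerate_covariance",
             "sample covariance is singular; fall back to the product kernel (kde_marginal)")
  det_half <- prod(diag(ch))          # det(S)^{1/2}
  out <- numeric(nrow(pts))
  const <- (2 * pi)^(-d / 2) / (n * h^d * det_half)
  for (m in seq_len(nrow(pts))) {
    delta <- t(data) - pts[m, ]       # d x n
    z <- backsolve(ch, delta, transpose = TRUE)
    q <- colSums(z * z) / h^2
    out[m] <- const * sum(exp(-q / 2))
  }
  out
}

coerce_points <- function(points, d) {
  if (is.matrix(points)) {
    if (ncol(points) != d)
      qr_error("qr_invalid_input",
               sprintf("evaluation points have %d columns, data has %d",
                       ncol(points), d))
    pts <- points
  } else {
    if (length(points) != d && d != 1L)
      qr_error("qr_invalid_input",
               sprintf("point length %d does not match dimension %d",
                       length(points), d))
    pts <- if (d == 1L) matrix(points, ncol = 1L) else matrix(points, nrow = 1L)
  }
  if (!all(is.finite(pts)))
    qr_error("qr_invalid_input", "non-finite evaluation point")
  pts
}
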