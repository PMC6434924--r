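#' Check (pinball) loss
#'
#' \eqn{\rho_\tau(u) = u(\tau - I(u < 0))}: weight `tau` on positive
#' residuals, `1 - tau` on negative ones.  The minimizer of its sum is the
#' tau-th quantile.
#'
#' @param u numeric residual(s).
#' @param tau quantile level in (0, 1).
#' @return nonnegative value(s), zero exactly at `u = 0`.
#' @export
check_loss <- function(u, tau) {
  check_tau(tau)
  if (!is.numeric(u)) qr_error("qr_invalid_input", "u must be numeric")
  u * (tau - (u < 0))
}

#' Linear quantile regression fit
#'
#' Minimizes the total check loss
#' \eqn{\sum_i \rho_\tau(y_i - x_{p i}^T \beta)} over the affine
#' coefficients, i.e. solves the linear program
#' \deqn{\min \{\tau 1' u + (1-\tau) 1' v : X\beta + u - v = y,\ u, v \ge 0\}.}
#' With no covariate or one covariate the program is solved exactly by
#' enumerating its basic solutions (an optimal vertex interpolates p data
#' points); for d >= 2 a majorize-minimize iteration with a combinatorial
#' polishing step over near-active observations is used.
#'
#' @param sample a [regression_sample()]; `d = 0` gives the sample
#'   quantile.
#' @param tau quantile level in (0, 1).
#' @return object of class `linear_qr_fit`: `tau`, `beta` (intercept
#'   first), `objective` (achieved check-loss sum), `n_interpolated`
#'   (residuals at zero within tolerance).
#' @export
fit_linear_qr <- function(sample, tau) {
  sample <- as_sample(sample)
  check_tau(tau)
  if (length(tau) != 1L) qr_error("qr_invalid_input", "tau must be a scalar")
  y <- sample$y; X <- sample$X
  p <- sample$d + 1L
  Xp <- cbind(1, X)
  if (qr(Xp)$rank < p)
    qr_error("qr_degenerate_design",
             "design matrix [1 X] is rank deficient")
  if (sample$d == 0L) {
    b0 <- cpp_weighted_quantile(y, rep(1, sample$n), tau)
    beta <- b0
  } else if (sample$d == 1L) {
    fit <- cpp_qr_pairs(X[, 1L], y, rep(1, sample$n), tau)
    if (fit$status != 0L)
      qr_error("qr_degenerate_design", "fewer than two distinct x values")
    beta <- c(fit$intercept, fit$slope)
  } else {
    beta <- qr_fit_mm(Xp, y, rep(1, sample$n), tau)
  }
  r <- y - as.vector(Xp %*% beta)
  objective <- sum(check_loss(r, tau))
  tol <- 1e-8 * (1 + max(abs(y)))
  structure(list(tau = tau, beta = as.numeric(beta), objective = objective,
                 n_interpolated = sum(abs(r) < tol)),
            class = "linear_qr_fit")
}

#' @export
print.linear_qr_fit <- function(x, ...) {
  cat("<linear_qr_fit> tau =", x$tau,
      " beta = (", paste(signif(x$beta, 5), collapse = ", "), ")",
      " objective =", signif(x$objective, 6), "\n")
  invisible(x)
}

# majorize-minimize iteration for weighted check loss (p >= 3), followed by
# exact refits through subsets of the near-active observations; returns the
# best coefficient vector found
qr_fit_mm <- function(Xp, y, w, tau, maxit = 400L) {
  p <- ncol(Xp)
  beta <- qr.coef(qr(Xp * sqrt(w)), y * sqrt(w))
  eps <- 1e-5 * (stats::sd(y) + 1e-12)
  xw <- colSums(Xp * w)
  objective <- function(b) sum(w * check_loss(y - as.vector(Xp %*% b), tau))
  last <- objective(beta)
  for (it in seq_len(maxit)) {
    r <- y - as.vector(Xp %*% beta)
    D <- w / (2 * (abs(r) + eps))
    A <- crossprod(Xp, Xp * D)
    rhs <- crossprod(Xp, D * y) + (tau - 0.5) * xw
    beta_new <- tryCatch(solve(A, rhs), error = function(e) beta)
    cur <- objective(beta_new)
    if (cur <= last) beta <- beta_new
    if (abs(last - cur) < 1e-12 * (1 + last)) {
      if (eps <= 1e-12) break
      eps <- eps / 10
    }
    last <- min(last, cur)
  }
  # polish: exact interpolating refits through p of the 2p nearest-to-active
  r <- y - as.vector(Xp %*% beta)
  cand <- order(abs(r))[seq_len(min(2L * p, length(y)))]
  best <- beta; best_obj <- objective(beta)
  for (set in utils::combn(cand, p, simplify = FALSE)) {
    XB <- Xp[set, , drop = FALSE]
    if (abs(det(XB)) < 1e-10) next
    b <- tryCatch(solve(XB, y[set]), error = function(e) NULL)
    if (is.null(b)) next
    ob <- objective(b)
    if (ob < best_obj - 1e-12) { best <- b; best_obj <- ob }
  }
  as.numeric(best)
}

#' Evaluate a linear quantile regression fit on a grid
#'
#' Affine evaluation \eqn{Q_R(\tau | x) = \hat\beta_0 + \hat\beta^T x}.
#'
#' @param fit a `linear_qr_fit`.
#' @param x_eval numeric vector (d = 1) or m x d matrix of evaluation
#'   points.
#' @return a [quantile_curve()] with method `"linear"`.
#' @export
predict_linear_qr <- function(fit, x_eval) {
  if (!inherits(fit, "linear_qr_fit"))
    qr_error("qr_invalid_input", "fit must be a linear_qr_fit")
  d <- length(fit$beta) - 1L
  xmat <- if (is.matrix(x_eval)) x_eval
          else matrix(x_eval, ncol = max(d, 1L))
  if (d == 0L) xmat <- matrix(x_eval, ncol = 1L)   # grid kept for plotting
  if (d >= 1L && ncol(xmat) != d)
    qr_error("qr_invalid_input",
             sprintf("x_eval has %d columns, fit has %d covariates",
                     ncol(xmat), d))
  q <- if (d == 0L) rep(fit$beta[1L], nrow(xmat))
       else as.vector(cbind(1, xmat) %*% fit$beta)
  quantile_curve(fit$tau, xmat, q, "linear",
                 provenance = list(beta = fit$beta,
                                   objective = fit$objective))
}

#' Local-linear (first-order polynomial) quantile regression at a point
#'
#' Minimizes the Gaussian-kernel-weighted check loss
#' \eqn{\sum_i \rho_\tau\{y_i - a_0 - a_1 (x_i - x_0)\} K\{(x_0 - x_i)/h\}}
#' exactly, as a weighted check-loss linear program solved by basic-solution
#' enumeration.  One covariate only.
#'
#' @param sample a [regression_sample()] with `d = 1`.
#' @param tau quantile level in (0, 1).
#' @param x0 evaluation point.
#' @param h positive bandwidth; default twice the per-dimension plug-in
#'   bandwidth of the covariate.
#' @param intercept_only constrain the slope to zero (local constant fit);
#'   ties break toward the smaller candidate value.
#' @return object of class `lpqr_fit`: `tau`, `x0`, `a0` (the fitted
#'   conditional quantile at `x0`), `a1`, `bandwidth`, `objective`.
#' @export
fit_lpqr <- function(sample, tau, x0, h = NULL, intercept_only = FALSE) {
  sample <- as_sample(sample)
  check_tau(tau)
  if (sample$d != 1L)
    qr_error("qr_invalid_input", "local polynomial fit requires exactly one covariate")
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0))
    qr_error("qr_invalid_input", "x0 must be a finite scalar")
  x <- sample$X[, 1L]; y <- sample$y
  if (is.null(h)) h <- 2 * per_dimension_bandwidth(x, sample$n)
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || !is.finite(h))
    qr_error("qr_invalid_input", "h must be a positive scalar")
  w <- exp(-0.5 * ((x0 - x) / h)^2)
  live <- w > 1e-12 * max(w)
  if (sum(live) < 2L)
    qr_error("qr_insufficient_local_data",
             sprintf("fewer than 2 observations with kernel weight at x0 = %g", x0))
  if (intercept_only) {
    a0 <- cpp_weighted_quantile(y[live], w[live], tau)
    a1 <- 0
    objective <- sum(w[live] * check_loss(y[live] - a0, tau))
  } else {
    if (length(unique(x[live])) < 2L)
      qr_error("qr_insufficient_local_data",
               sprintf("fewer than 2 distinct covariate values near x0 = %g", x0))
    fit <- cpp_qr_pairs(x[live], y[live], w[live], tau)
    a0 <- fit$intercept + fit$slope * x0
    a1 <- fit$slope
    objective <- fit$objective
  }
  structure(list(tau = tau, x0 = x0, a0 = as.numeric(a0),
                 a1 = as.numeric(a1), bandwidth = h,
                 objective = as.numeric(objective)),
            class = "lpqr_fit")
}

#' @export
print.lpqr_fit <- function(x, ...) {
  cat("<lpqr_fit> tau =", x$tau, " x0 =", x$x0,
      " a0 =", signif(x$a0, 5), " a1 =", signif(x$a1, 5),
      " h =", signif(x$bandwidth, 4), "\n")
  invisible(x)
}

#' Local-linear quantile regression curve
#'
#' [fit_lpqr()] applied at every point of an evaluation grid, sharing the
#' kernel-weight and candidate-line work across quantile levels.  Grid
#' points outside the observed covariate range are clamped to the nearest
#' data boundary (constant extension), so the local line is never
#' extrapolated beyond the data; grid points whose effective window holds
#' fewer than two distinct covariate values fall back to a local weighted
#' quantile (slope zero).  Both fallbacks are counted in provenance.
#'
#' @inheritParams fit_lpqr
#' @param taus one or more quantile levels.
#' @param x_eval evaluation grid (numeric vector).
#' @return a [quantile_curve()] (or list of them) with method `"lpqr"`.
#' @export
lpqr_curve <- function(sample, taus, x_eval, h = NULL) {
  sample <- as_sample(sample)
  check_tau(taus)
  if (sample$d != 1L)
    qr_error("qr_invalid_input", "local polynomial fit requires exactly one covariate")
  if (is.null(h)) h <- 2 * per_dimension_bandwidth(sample$X[, 1L], sample$n)
  res <- cpp_lpqr_curve(sample$X[, 1L], sample$y, as.numeric(x_eval),
                        taus, h)
  prov <- list(bandwidth = h, n_degenerate_windows = sum(res$flag == 1L),
               n_clamped = sum(res$flag == 2L))
  curves <- lapply(seq_along(taus), function(k)
    quantile_curve(taus[k], matrix(x_eval, ncol = 1L), res$a0[, k], "lpqr",
                   provenance = c(prov, list(a1 = res$a1[, k]))))
  if (length(taus) == 1L) curves[[1L]] else curves
}
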