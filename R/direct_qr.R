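#' Regression sample container
#'
#' Holds a response vector and covariate matrix, the raw input to every
#' estimator in the package.
#'
#' @param y numeric response vector of length n.
#' @param X covariate matrix (n x d), a numeric vector (treated as one
#'   column), or `NULL` for an intercept-only design (d = 0).
#' @param column_names optional covariate labels.
#' @return object of class `regression_sample` with elements `y`, `X`, `n`,
#'   `d`.
#' @export
regression_sample <- function(y, X = NULL, column_names = NULL) {
  if (!is.numeric(y) || length(y) < 1L || !all(is.finite(y)))
    qr_error("qr_invalid_input", "y must be a finite numeric vector")
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  } else {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
  }
  if (nrow(X) != length(y))
    qr_error("qr_invalid_input", "y and X must have the same number of rows")
  if (ncol(X) > 0L && !all(is.finite(X)))
    qr_error("qr_invalid_input", "X must be finite")
  if (!is.null(column_names)) colnames(X) <- column_names
  else if (is.null(colnames(X)) && ncol(X) > 0L)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(y = as.numeric(y), X = X,
                 n = length(y), d = ncol(X)),
            class = "regression_sample")
}

#' @export
print.regression_sample <- function(x, ...) {
  cat("<regression_sample> n =", x$n, " d =", x$d, "\n")
  invisible(x)
}

as_sample <- function(sample) {
  if (!inherits(sample, "regression_sample"))
    qr_error("qr_invalid_input", "expected a regression_sample")
  sample
}

# ---------------------------------------------------------------------------
# bandwidth defaults for the density stage (Step 1)
#
# whitened: scale-free scalar rules, dimension of each estimator
#   (p = d+1 for the joint, d for the marginal of x)
# product:  per-dimension plug-in bandwidths; the marginal of x reuses the
#   joint's x-bandwidths so the conditional density integrates to one
#   exactly (up to grid truncation)
density_bandwidths <- function(sample, kernel_type, bw = NULL) {
  n <- sample$n; d <- sample$d
  if (kernel_type == "whitened") {
    if (is.null(bw)) {
      h_joint <- normal_reference_bandwidth(n, d + 1L)
      h_marg  <- if (d >= 1L) normal_reference_bandwidth(n, d) else NA_real_
      rule <- "normal_reference_multivariate"
    } else {
      v <- if (inherits(bw, "bandwidth_spec")) bw$values else bw
      if (length(v) != 1L || v <= 0 || !is.finite(v))
        qr_error("qr_invalid_input", "whitened kernel takes one scalar bandwidth")
      h_joint <- v
      h_marg  <- v
      rule <- "user_fixed"
    }
    hy_eff <- h_joint * stats::sd(sample$y)
    list(type = "whitened", h_joint = h_joint, h_marg = h_marg,
         hy_eff = hy_eff, rule = rule)
  } else {
    if (is.null(bw)) {
      hy <- per_dimension_bandwidth(sample$y, n)
      hx <- if (d >= 1L) apply(sample$X, 2L, per_dimension_bandwidth, n = n)
            else numeric(0)
      rule <- "normal_reference_per_dim"
    } else {
      v <- bw_values(bw, d + 1L)
      hy <- v[1L]; hx <- v[-1L]
      rule <- "user_fixed"
    }
    list(type = "product", hy = hy, hx = hx, hy_eff = hy, rule = rule)
  }
}

#' Default response grid for conditional CDF inversion
#'
#' Uniform grid from `min(y) - 4 h_y` to `max(y) + 8 h_y` with `nodes`
#' points; the extra right-tail headroom keeps high-quantile inversion off
#' the grid edge. `h_y` is the effective response-direction bandwidth of
#' the joint density estimate.
#'
#' @param sample a [regression_sample()].
#' @param kernel_type `"whitened"` or `"product"` joint density estimator.
#' @param nodes number of grid nodes (default 1024).
#' @param widen nonnegative integer; each unit doubles the margins (used by
#'   the automatic grid-coverage recovery).
#' @param bw optional bandwidth override, as in [conditional_density()].
#' @return increasing numeric vector.
#' @export
default_y_grid <- function(sample, kernel_type = c("whitened", "product"),
                           nodes = 1024L, widen = 0L, bw = NULL) {
  sample <- as_sample(sample)
  kernel_type <- match.arg(kernel_type)
  bws <- density_bandwidths(sample, kernel_type, bw)
  y_grid_from_bws(sample, bws, nodes, widen)
}

y_grid_from_bws <- function(sample, bws, nodes, widen) {
  mult <- 2^widen
  lo <- min(sample$y) - 4 * bws$hy_eff * mult
  hi <- max(sample$y) + 8 * bws$hy_eff * mult
  seq(lo, hi, length.out = nodes)
}

# ---------------------------------------------------------------------------
# density-stage engine: joint density slices f^(y, x0) on a y-grid, the
# closed-form infinite-domain integral of each slice (for the grid-coverage
# check), and the marginal g^(x0), for a matrix of evaluation points

joint_slices <- function(sample, xmat, y_grid, bws) {
  y <- sample$y; X <- sample$X
  n <- sample$n; d <- sample$d
  m <- nrow(xmat); G <- length(y_grid)
  DY <- outer(y_grid, y, "-")                     # G x n, shared
  J <- matrix(0, G, m); total <- numeric(m)
  if (bws$type == "whitened") {
    p <- d + 1L
    h <- bws$h_joint
    Z <- cbind(y, X)
    S <- stats::cov(Z)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      qr_error("qr_degenerate_covariance",
               "joint sample covariance is singular; use kernel_type = 'product'")
    A <- chol2inv(ch)
    a <- A[1L, 1L]
    K <- (2 * pi)^(-p / 2) / (n * h^p * prod(diag(ch)))
    if (d == 0L) {
      q0 <- a * DY^2
      J[] <- K * rowSums(exp(-q0 / (2 * h^2)))
      total[] <- K * n * sqrt(2 * pi * h^2 / a)
    } else {
      B <- A[1L, -1L]
      C <- A[-1L, -1L, drop = FALSE]
      for (mm in seq_len(m)) {
        DX <- matrix(xmat[mm, ], n, d, byrow = TRUE) - X   # x0 - X_i
        u <- as.vector(DX %*% B)
        cc <- rowSums((DX %*% C) * DX)
        Q <- a * DY^2 + DY * rep(2 * u, each = G) +
          matrix(cc, G, n, byrow = TRUE)
        J[, mm] <- K * rowSums(exp(-Q / (2 * h^2)))
        total[mm] <- K * sqrt(2 * pi * h^2 / a) *
          sum(exp(-(cc - u^2 / a) / (2 * h^2)))
      }
    }
  } else {
    hy <- bws$hy; hx <- bws$hx
    PHI <- stats::dnorm(DY / hy) / hy               # G x n, shared
    if (d == 0L) {
      J[] <- rowMeans(PHI)
      total[] <- 1
    } else {
      for (mm in seq_len(m)) {
        lw <- 0
        for (j in seq_len(d))
          lw <- lw + stats::dnorm((xmat[mm, j] - X[, j]) / hx[j], log = TRUE) -
            log(hx[j])
        w <- exp(lw)
        J[, mm] <- PHI %*% w / n
        total[mm] <- sum(w) / n
      }
    }
  }
  list(J = J, total = total)
}

marginal_g <- function(sample, xmat, bws) {
  d <- sample$d
  if (d == 0L) return(rep(1, nrow(xmat)))
  if (bws$type == "whitened")
    kde_whitened(sample$X, xmat, bws$h_marg)
  else
    kde_marginal(sample$X, xmat, bws$hx)
}

cumtrapz <- function(grid, f) {
  # cumulative trapezoid along the first axis of matrix f (grid x m)
  dg <- diff(grid)
  inc <- 0.5 * dg * (f[-1L, , drop = FALSE] + f[-length(grid), , drop = FALSE])
  rbind(0, apply(inc, 2L, cumsum))
}

trapz <- function(grid, f) {
  dg <- diff(grid)
  if (is.matrix(f))
    colSums(0.5 * dg * (f[-1L, , drop = FALSE] + f[-nrow(f), , drop = FALSE]))
  else
    sum(0.5 * dg * (f[-1L] + f[-length(f)]))
}

# full CDF engine with automatic grid widening; xmat is m x d
cond_cdf_engine <- function(sample, xmat, kernel_type, bw = NULL,
                            y_grid = NULL, nodes = 1024L,
                            auto_widen = TRUE, max_widen = 4L) {
  bws <- density_bandwidths(sample, kernel_type, bw)
  user_grid <- !is.null(y_grid)
  widen <- 0L
  repeat {
    if (!user_grid)
      y_grid <- y_grid_from_bws(sample, bws, nodes, widen)
    js <- joint_slices(sample, xmat, y_grid, bws)
    coverage <- trapz(y_grid, js$J) / js$total
    if (min(coverage) >= 0.995 || user_grid || !auto_widen ||
        widen >= max_widen)
      break
    widen <- widen + 1L
  }
  if (min(coverage) < 0.95)
    qr_error("qr_grid_coverage",
             sprintf(paste0("response grid captures only %.3f of the joint ",
                            "density mass at x = (%s); widen the grid"),
                     min(coverage),
                     paste(signif(xmat[which.min(coverage), ], 4),
                           collapse = ", ")))
  ghat <- marginal_g(sample, xmat, bws)
  if (any(ghat < 1e-300))
    qr_error("qr_unsupported_point",
             sprintf("marginal density underflows at x = (%s); point outside the support of the data",
                     paste(signif(xmat[which(ghat < 1e-300)[1L], ], 4),
                           collapse = ", ")))
  f <- sweep(js$J, 2L, ghat, "/")
  Fmat <- cumtrapz(y_grid, f)
  raw_total <- Fmat[nrow(Fmat), ]
  Fnorm <- sweep(Fmat, 2L, raw_total, "/")
  list(y_grid = y_grid, pdf = f, cdf = Fnorm, raw_total = raw_total,
       coverage = coverage, ghat = ghat, bws = bws, widen = widen)
}

# monotone linear interpolation of the smallest y with F(y) >= tau
invert_cdf <- function(y_grid, Fvec, taus) {
  vapply(taus, function(tau) {
    k <- which(Fvec >= tau)[1L]
    if (is.na(k)) return(y_grid[length(y_grid)])
    if (k == 1L) return(y_grid[1L])
    f0 <- Fvec[k - 1L]; f1 <- Fvec[k]
    if (f1 <= f0) return(y_grid[k])
    y_grid[k - 1L] + (tau - f0) / (f1 - f0) * (y_grid[k] - y_grid[k - 1L])
  }, numeric(1L))
}

#' Kernel conditional density on a response grid
#'
#' Step 1 of the direct method: the conditional density of the response
#' given covariates `x0`, estimated as the ratio of a (d+1)-dimensional
#' joint kernel density estimate to the d-dimensional marginal estimate at
#' `x0`.
#'
#' @param sample a [regression_sample()].
#' @param x0 covariate point (length-d vector).
#' @param y_grid increasing response grid; default [default_y_grid()].
#' @param bw optional bandwidth override (scalar for `whitened`, length
#'   d+1 vector for `product`); `NULL` applies the plug-in rules.
#' @param kernel_type `"whitened"` (covariance-whitened joint kernel,
#'   default) or `"product"` (per-dimension product kernel).
#' @return nonnegative density values on `y_grid`.
#' @export
conditional_density <- function(sample, x0, y_grid = NULL, bw = NULL,
                                kernel_type = c("whitened", "product")) {
  sample <- as_sample(sample)
  kernel_type <- match.arg(kernel_type)
  xmat <- coerce_points(x0, sample$d)
  eng <- cond_cdf_engine(sample, xmat, kernel_type, bw = bw,
                         y_grid = y_grid, auto_widen = is.null(y_grid))
  structure(eng$pdf[, 1L], y_grid = eng$y_grid)
}

#' Kernel conditional CDF on a response grid
#'
#' Step 2: running trapezoid integral of [conditional_density()],
#' renormalized by its final value so the inversion in Step 3 is
#' well-defined near `tau = 1`.  A grid-coverage check compares the grid
#' integral of the joint density slice against its closed-form
#' infinite-domain value; the default grid is widened automatically until
#' at least 99.5% of the mass is captured (error below 95%).
#'
#' @inheritParams conditional_density
#' @param renormalize divide by the final raw value (default `TRUE`).
#' @return nondecreasing values in `[0, 1]` with attributes `raw_total`
#'   (the unnormalized final integral), `coverage` and `y_grid`.
#' @export
conditional_cdf <- function(sample, x0, y_grid = NULL, bw = NULL,
                            kernel_type = c("whitened", "product"),
                            renormalize = TRUE) {
  sample <- as_sample(sample)
  kernel_type <- match.arg(kernel_type)
  xmat <- coerce_points(x0, sample$d)
  eng <- cond_cdf_engine(sample, xmat, kernel_type, bw = bw,
                         y_grid = y_grid, auto_widen = is.null(y_grid))
  out <- if (renormalize) eng$cdf[, 1L] else eng$cdf[, 1L] * eng$raw_total[1L]
  structure(out, raw_total = eng$raw_total[1L], coverage = eng$coverage[1L],
            y_grid = eng$y_grid)
}

#' Local conditional quantile at one data point
#'
#' Step 3: inverts the estimated conditional CDF at the covariates of one
#' sample row, returning the smallest grid-interpolated y with
#' \eqn{\hat F(y | x_i) \ge \tau}.
#'
#' @inheritParams conditional_density
#' @param row_index which sample row to invert at.
#' @param tau quantile level in (0, 1).
#' @return a single local quantile value.
#' @export
local_quantile <- function(sample, row_index, tau, bw = NULL,
                           kernel_type = c("whitened", "product"),
                           y_grid = NULL) {
  sample <- as_sample(sample)
  kernel_type <- match.arg(kernel_type)
  check_tau(tau)
  if (!is.numeric(row_index) || length(row_index) != 1L ||
      row_index < 1L || row_index > sample$n)
    qr_error("qr_invalid_input", "row_index out of range")
  xmat <- sample$X[row_index, , drop = FALSE]
  eng <- cond_cdf_engine(sample, xmat, kernel_type, bw = bw,
                         y_grid = y_grid, auto_widen = is.null(y_grid))
  invert_cdf(eng$y_grid, eng$cdf[, 1L], tau)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0) ||
      any(tau >= 1))
    qr_error("qr_invalid_input", "tau must lie strictly between 0 and 1")
  invisible(tau)
}

# local quantiles at every sample row for a vector of taus (n x T matrix);
# the expensive CDF pass is shared across taus
local_quantile_matrix <- function(sample, taus, kernel_type = "whitened",
                                  bw = NULL, y_grid = NULL, nodes = 1024L) {
  check_tau(taus)
  eng <- cond_cdf_engine(sample, sample$X, kernel_type, bw = bw,
                         y_grid = y_grid, nodes = nodes,
                         auto_widen = is.null(y_grid))
  xi <- t(apply(eng$cdf, 2L, function(Fv) invert_cdf(eng$y_grid, Fv, taus)))
  if (length(taus) == 1L) xi <- matrix(xi, ncol = 1L)
  attr(xi, "engine") <- eng[c("y_grid", "coverage", "bws", "widen")]
  xi
}

#' Local quantile set (Step 3 at every data point)
#'
#' The n pairs \eqn{(x_i, \hat\xi_i(\tau | x_i))} obtained by inverting the
#' conditional CDF at each sample row; the intermediate product the direct
#' estimator smooths in Step 4.
#'
#' @inheritParams conditional_density
#' @param tau single quantile level in (0, 1).
#' @return object of class `local_quantile_set` with elements `tau`, `x`
#'   (the covariate matrix), `xi` (the n local quantiles), `bandwidths` and
#'   `grid_meta`.
#' @export
local_quantile_set <- function(sample, tau, bw = NULL,
                               kernel_type = c("whitened", "product"),
                               y_grid = NULL) {
  sample <- as_sample(sample)
  kernel_type <- match.arg(kernel_type)
  xi <- local_quantile_matrix(sample, tau, kernel_type, bw, y_grid)
  eng <- attr(xi, "engine")
  structure(list(tau = tau, x = sample$X, xi = as.vector(xi[, 1L]),
                 bandwidths = eng$bws,
                 grid_meta = list(range = range(eng$y_grid),
                                  nodes = length(eng$y_grid),
                                  widened = eng$widen)),
            class = "local_quantile_set")
}

#' @export
print.local_quantile_set <- function(x, ...) {
  cat("<local_quantile_set> tau =", x$tau, " n =", length(x$xi),
      " xi range = [", signif(min(x$xi), 4), ",", signif(max(x$xi), 4), "]\n")
  invisible(x)
}

#' Nadaraya-Watson equivalent-kernel weights
#'
#' The normalized Gaussian product-kernel weights
#' \eqn{W_h(x_0, X_i) = K_h(x_0 - X_i) / \sum_j K_h(x_0 - X_j)}:
#' nonnegative, summing to one, and invariant to a common positive
#' rescaling of the kernel terms.
#'
#' @param x0 evaluation point (length-d vector).
#' @param X n x d covariate matrix (or vector).
#' @param bw bandwidth(s): scalar, length-d, or a [bandwidth_spec].
#' @return numeric weight vector of length n.
#' @export
nw_weights <- function(x0, X, bw) {
  X <- as.matrix(X)
  d <- ncol(X)
  xmat <- coerce_points(x0, d)
  h <- bw_values(bw, d)
  lw <- 0
  for (j in seq_len(d))
    lw <- lw + stats::dnorm((xmat[1L, j] - X[, j]) / h[j], log = TRUE)
  w <- exp(lw)
  s <- sum(w)
  if (s == 0)
    qr_error("qr_extrapolation",
             "all kernel weights underflow; x0 is too far outside the data")
  w / s
}

#' Quantile curve container
#'
#' An evaluated conditional quantile function on a covariate grid, with
#' provenance.
#'
#' @param tau quantile level.
#' @param x_eval evaluation grid (vector for d = 1 or m x d matrix).
#' @param q fitted conditional quantiles, one per grid point.
#' @param method `"direct"`, `"linear"` or `"lpqr"`.
#' @param provenance free-form list (bandwidths, coefficients, seeds).
#' @return object of class `quantile_curve`.
#' @export
quantile_curve <- function(tau, x_eval, q, method, provenance = list()) {
  check_tau(tau)
  x_eval <- as.matrix(x_eval)
  if (length(q) != nrow(x_eval) || !all(is.finite(q)))
    qr_error("qr_invalid_input", "q must be finite, one value per grid point")
  structure(list(tau = tau, x_eval = x_eval, q = as.numeric(q),
                 method = match.arg(method, c("direct", "linear", "lpqr")),
                 provenance = provenance),
            class = "quantile_curve")
}

#' @export
print.quantile_curve <- function(x, ...) {
  cat("<quantile_curve>", x$method, " tau =", x$tau,
      " points =", nrow(x$x_eval),
      " q range = [", signif(min(x$q), 4), ",", signif(max(x$q), 4), "]\n")
  invisible(x)
}

#' Direct nonparametric quantile curves (Steps 1-4)
#'
#' The full direct estimator for one or more quantile levels: local
#' conditional quantiles are computed at every sample row by kernel
#' conditional-CDF inversion, then smoothed with Nadaraya-Watson
#' equivalent-kernel weights at each evaluation point.  All levels share
#' one conditional-CDF pass, and the shared nonnegative weights make the
#' returned curves non-crossing whenever the local quantiles are monotone
#' in `tau` (which the monotone CDF inversion guarantees).
#'
#' Evaluation points where every kernel weight underflows (far outside the
#' covariate range) fall back to the local quantile of the nearest data
#' point, with a warning.
#'
#' @inheritParams conditional_density
#' @param taus one or more quantile levels in (0, 1).
#' @param x_eval evaluation grid; default 101 equispaced points over the
#'   covariate range (d = 1 only).
#' @param bw_density bandwidth override for the density stage (Step 1).
#' @param bw_smooth bandwidth(s) for the smoothing stage (Step 4); default
#'   is the per-dimension plug-in rule [bw_per_dimension()].
#' @return a single [quantile_curve()] when `length(taus) == 1`, otherwise
#'   a list of them (one per level, in the order given).
#' @export
direct_quantile_curve <- function(sample, taus, x_eval = NULL,
                                  bw_density = NULL, bw_smooth = NULL,
                                  kernel_type = c("whitened", "product"),
                                  y_grid = NULL) {
  sample <- as_sample(sample)
  kernel_type <- match.arg(kernel_type)
  if (sample$d < 1L)
    qr_error("qr_invalid_input", "direct curves need at least one covariate")
  if (is.null(x_eval)) {
    if (sample$d != 1L)
      qr_error("qr_invalid_input", "supply x_eval when d > 1")
    x_eval <- seq(min(sample$X), max(sample$X), length.out = 101L)
  }
  xmat <- if (is.matrix(x_eval)) x_eval else matrix(x_eval, ncol = sample$d)
  if (!all(is.finite(xmat)))
    qr_error("qr_invalid_input", "x_eval must be finite")
  if (is.null(bw_smooth)) bw_smooth <- bw_per_dimension(sample$X, sample$n)
  h <- bw_values(bw_smooth, sample$d)

  xi <- local_quantile_matrix(sample, taus, kernel_type, bw_density, y_grid)
  eng <- attr(xi, "engine")

  # weight matrix (m x n) in one vectorized pass per dimension
  m <- nrow(xmat)
  lw <- matrix(0, m, sample$n)
  for (j in seq_len(sample$d))
    lw <- lw + stats::dnorm(outer(xmat[, j], sample$X[, j], "-") / h[j],
                            log = TRUE)
  W <- exp(lw)
  s <- rowSums(W)
  dead <- which(s == 0)
  if (length(dead) > 0L) {
    # nearest-data-point fallback on the bandwidth-scaled metric
    Xs <- sweep(sample$X, 2L, h, "/")
    for (mm in dead) {
      z <- sweep(Xs, 2L, xmat[mm, ] / h, "-")
      k <- which.min(rowSums(z * z))
      W[mm, ] <- 0; W[mm, k] <- 1; s[mm] <- 1
    }
    qr_warn("qr_extrapolation_warning",
            sprintf("%d evaluation point(s) outside kernel support; used nearest data point", length(dead)))
  }
  Q <- (W / s) %*% xi

  prov <- list(bw_density = eng$bws, bw_smooth = h,
               grid_meta = list(range = range(eng$y_grid),
                                nodes = length(eng$y_grid)),
               extrapolated = length(dead))
  curves <- lapply(seq_along(taus), function(k)
    quantile_curve(taus[k], xmat, Q[, k], "direct", prov))
  if (length(taus) == 1L) curves[[1L]] else curves
}

#' Diagnostics for fitted quantile curves (Step 5)
#'
#' Read-only checks on a set of fitted curves: crossing violations across
#' levels, empirical coverage of the sample below each curve versus the
#' nominal level, and grid-coverage notes carried in provenance.
#'
#' @param curves a [quantile_curve()] or list of them sharing one
#'   evaluation grid.
#' @param sample the [regression_sample()] the curves were fitted to.
#' @return object of class `qr_diagnostics`: a list with a `summary` data
#'   frame (tau, method, empirical coverage, extrapolated-point count from
#'   provenance) and a `crossings` data frame.
#' @export
diagnose <- function(curves, sample) {
  sample <- as_sample(sample)
  if (inherits(curves, "quantile_curve")) curves <- list(curves)
  if (length(curves) < 1L) qr_error("qr_invalid_input", "no curves supplied")
  taus <- vapply(curves, `[[`, numeric(1L), "tau")
  cover <- vapply(curves, function(cv) {
    if (sample$d == 1L && nrow(cv$x_eval) > 1L) {
      qx <- stats::approx(cv$x_eval[, 1L], cv$q, xout = sample$X[, 1L],
                          rule = 2L)$y
      mean(sample$y <= qx)
    } else NA_real_
  }, numeric(1L))
  extrap <- vapply(curves, function(cv) {
    e <- cv$provenance$extrapolated
    if (is.null(e)) 0L else as.integer(e)
  }, integer(1L))
  summary <- data.frame(tau = taus,
                        method = vapply(curves, `[[`, character(1L), "method"),
                        coverage = cover,
                        n_extrapolated = extrap)
  ord <- order(taus)
  cross <- NULL
  if (length(curves) >= 2L) {
    for (k in seq_len(length(ord) - 1L)) {
      a <- curves[[ord[k]]]; b <- curves[[ord[k + 1L]]]
      if (nrow(a$x_eval) == nrow(b$x_eval)) {
        nviol <- sum(a$q > b$q + 1e-8)
        cross <- rbind(cross,
                       data.frame(tau_low = a$tau, tau_high = b$tau,
                                  n_violations = nviol))
      }
    }
  }
  if (is.null(cross))
    cross <- data.frame(tau_low = numeric(0), tau_high = numeric(0),
                        n_violations = integer(0))
  structure(list(summary = summary, crossings = cross),
            class = "qr_diagnostics")
}

#' @export
print.qr_diagnostics <- function(x, ...) {
  cat("<qr_diagnostics>\n")
  print(x$summary, row.names = FALSE)
  if (nrow(x$crossings) > 0L) {
    nv <- sum(x$crossings$n_violations)
    cat(if (nv > 0L) sprintf("crossing violations: %d\n", nv)
        else "no crossing violations\n")
  }
  invisible(x)
}
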