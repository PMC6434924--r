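#' Monte-Carlo study configuration
#'
#' Describes one simulation experiment: `m` replicate samples of size `n`
#' from the bivariate exponential with dependence `alpha`, each estimator
#' fitted at every `tau`, and integrated squared error measured over
#' `x` in `[0, N]` by quadrature.
#'
#' @param m number of replicates (>= 2).
#' @param n sample size per replicate (>= 2).
#' @param taus quantile levels in (0, 1).
#' @param alpha dependence parameter in `[-1, 1]`.
#' @param N upper integration limit; must satisfy
#'   `gumbel_joint_cdf(N, N) >= 0.99`.
#' @param x_nodes quadrature node count on `[0, N]` (default 121, i.e.
#'   step 0.05 at `N = 6`).
#' @param seed master seed; replicate seeds are derived from it.
#' @param estimators subset of `c("direct", "linear", "lpqr")`.
#' @param lpqr_h optional fixed local-polynomial bandwidth (default: twice
#'   the per-dimension plug-in bandwidth of each replicate's x).
#' @param kernel_type joint-density estimator for the direct method.
#' @param verbose print one line per replicate.
#' @return object of class `study_config`.
#' @export
study_config <- function(m = 100L, n = 100L,
                         taus = c(0.95, 0.96, 0.97, 0.98, 0.99),
                         alpha = 1, N = 6, x_nodes = 121L, seed = 1L,
                         estimators = c("direct", "linear", "lpqr"),
                         lpqr_h = NULL,
                         kernel_type = c("whitened", "product"),
                         verbose = FALSE) {
  if (m < 2 || n < 2) qr_error("qr_invalid_input", "m and n must be >= 2")
  check_tau(taus)
  params <- gumbel_params(alpha)
  if (gumbel_joint_cdf(N, N, params) < 0.99)
    qr_error("qr_invalid_input",
             "N too small: joint CDF at (N, N) must be at least 0.99")
  estimators <- match.arg(estimators, c("direct", "linear", "lpqr"),
                          several.ok = TRUE)
  structure(list(m = as.integer(m), n = as.integer(n), taus = taus,
                 alpha = alpha, N = N, x_nodes = as.integer(x_nodes),
                 seed = as.integer(seed), estimators = estimators,
                 lpqr_h = lpqr_h, kernel_type = match.arg(kernel_type),
                 verbose = isTRUE(verbose)),
            class = "study_config")
}

#' Integrated squared error of one replicate curve
#'
#' Trapezoid approximation of
#' \eqn{\int_0^N \{Q(\tau | x) - Q_y(\tau | x)\}^2 dx} against the
#' closed-form true conditional quantile.
#'
#' @param curve a [quantile_curve()] evaluated on a grid spanning `[0, N]`,
#'   or a numeric vector of fitted values (then supply `x_grid`).
#' @param tau quantile level.
#' @param params a [gumbel_params()].
#' @param N upper integration limit.
#' @param x_grid quadrature grid (required when `curve` is numeric).
#' @return nonnegative scalar.
#' @export
smse_one_replicate <- function(curve, tau, params, N, x_grid = NULL) {
  if (inherits(curve, "quantile_curve")) {
    x_grid <- curve$x_eval[, 1L]
    q <- curve$q
  } else {
    q <- as.numeric(curve)
  }
  if (is.null(x_grid) || length(x_grid) != length(q))
    qr_error("qr_invalid_input", "need an x grid matching the curve values")
  if (min(x_grid) > 1e-9 || max(x_grid) < N - 1e-9)
    qr_error("qr_invalid_grid", "quadrature grid must span [0, N]")
  truth <- gumbel_conditional_quantile(tau, x_grid, params)
  trapz(x_grid, (q - truth)^2)
}

#' Run the Monte-Carlo efficiency study
#'
#' For each replicate, draws `n` pairs from the bivariate exponential, fits
#' the configured estimators at every quantile level, and accumulates the
#' integrated squared error against the true conditional quantile.  SMSE is
#' the replicate average; SEFF is the ratio of the linear baseline's SMSE
#' to a competitor's.  A replicate on which any estimator fails is
#' resampled from a fresh sub-stream (so averages stay over exactly `m`
#' replicates); more than 5% failures aborts the study.
#'
#' @param config a [study_config()].
#' @return object of class `simulation_report`: `smse` and `seff` matrices
#'   (estimator x tau), `config`, `replicate_seeds`, `n_resampled`.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config"))
    qr_error("qr_invalid_input", "expected a study_config")
  params <- gumbel_params(config$alpha)
  x_grid <- seq(0, config$N, length.out = config$x_nodes)
  taus <- config$taus
  ests <- config$estimators
  # replicate sub-stream seeds drawn once from the master seed; the tail of
  # the pool is a reserve for resampled replicates
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  pool <- sample.int(.Machine$integer.max - 1L, config$m + 200L)

  ise <- array(0, dim = c(length(ests), length(taus), config$m),
               dimnames = list(ests, paste0("tau", taus), NULL))
  used_seeds <- integer(config$m)
  n_resampled <- 0L
  next_reserve <- config$m
  r <- 1L
  while (r <= config$m) {
    seed_r <- pool[if (n_resampled == 0L || used_seeds[r] == 0L) r
                   else next_reserve]
    res <- tryCatch(
      one_replicate(seed_r, params, config, x_grid, taus),
      directqr_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      n_resampled <- n_resampled + 1L
      if (n_resampled > 0.05 * config$m + 1L)
        qr_error("qr_study_failed",
                 sprintf("more than 5%% of replicates failed (last: %s)",
                         conditionMessage(res)))
      next_reserve <- next_reserve + 1L
      used_seeds[r] <- -1L   # mark: use reserve on retry
      message(sprintf("replicate %d failed (%s); resampling", r,
                      conditionMessage(res)))
      next
    }
    ise[, , r] <- res
    used_seeds[r] <- seed_r
    if (config$verbose)
      message(sprintf("replicate %d/%d done", r, config$m))
    r <- r + 1L
  }
  smse <- apply(ise, c(1L, 2L), mean)
  seff <- matrix(numeric(0), 0L, length(taus),
                 dimnames = list(NULL, colnames(smse)))
  others <- setdiff(ests, "linear")
  if ("linear" %in% ests && length(others) > 0L) {
    seff <- smse[others, , drop = FALSE]
    for (e in others) seff[e, ] <- smse["linear", ] / smse[e, ]
  }
  structure(list(smse = smse, seff = seff, config = config,
                 replicate_seeds = used_seeds, n_resampled = n_resampled),
            class = "simulation_report")
}

# fit every configured estimator on one fresh sample; returns the
# (estimator x tau) matrix of integrated squared errors
one_replicate <- function(seed_r, params, config, x_grid, taus) {
  dat <- gumbel_sample(config$n, params, seed = seed_r)
  s <- regression_sample(dat$y, dat$x, column_names = "x")
  out <- matrix(NA_real_, length(config$estimators), length(taus))
  rownames(out) <- config$estimators
  for (est in config$estimators) {
    qhat <- switch(est,
      linear = {
        vapply(taus, function(tau) {
          fit <- fit_linear_qr(s, tau)
          as.vector(cbind(1, x_grid) %*% fit$beta)
        }, numeric(length(x_grid)))
      },
      lpqr = {
        h <- if (is.null(config$lpqr_h))
          2 * per_dimension_bandwidth(dat$x, config$n) else config$lpqr_h
        res <- cpp_lpqr_curve(dat$x, dat$y, x_grid, taus, h)
        res$a0
      },
      direct = {
        curves <- suppressWarnings(
          direct_quantile_curve(s, taus, x_eval = x_grid,
                                kernel_type = config$kernel_type))
        if (inherits(curves, "quantile_curve")) curves <- list(curves)
        vapply(curves, `[[`, numeric(length(x_grid)), "q")
      })
    out[est, ] <- vapply(seq_along(taus), function(k)
      smse_one_replicate(qhat[, k], taus[k], params, config$N, x_grid),
      numeric(1L))
  }
  out
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("<simulation_report> m =", x$config$m, " n =", x$config$n,
      " alpha =", x$config$alpha, " resampled =", x$n_resampled, "\n")
  cat(format_table1(x), sep = "\n")
  invisible(x)
}

#' Render a simulation report as a plain-text table
#'
#' SMSE rows (3 decimals) and efficiency rows (4 decimals) by quantile
#' level, in the conventional order linear, local polynomial, direct.
#'
#' @param report a `simulation_report`.
#' @return character vector of table lines.
#' @export
format_table1 <- function(report) {
  if (!inherits(report, "simulation_report"))
    qr_error("qr_invalid_input", "expected a simulation_report")
  taus <- report$config$taus
  labels <- c(linear = "SMSE(Q_R)", lpqr = "SMSE(Q_LP)",
              direct = "SMSE(Q_D)")
  efflab <- c(lpqr = "SEFF(Q_LP)", direct = "SEFF(Q_D)")
  want <- c("linear", "lpqr", "direct")
  have <- rownames(report$smse)
  if (!all(want %in% have))
    qr_warn("qr_partial_table",
            sprintf("estimators missing from report: %s",
                    paste(setdiff(want, have), collapse = ", ")))
  hdr <- paste0(format("tau", width = 12),
                paste(formatC(taus, format = "g", width = 9),
                      collapse = ""))
  lines <- hdr
  for (e in intersect(want, have))
    lines <- c(lines, paste0(format(labels[e], width = 12),
      paste(formatC(report$smse[e, ], format = "f", digits = 3,
                    width = 9), collapse = "")))
  for (e in intersect(names(efflab), rownames(report$seff)))
    lines <- c(lines, paste0(format(efflab[e], width = 12),
      paste(formatC(report$seff[e, ], format = "f", digits = 4,
                    width = 9), collapse = "")))
  lines
}
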