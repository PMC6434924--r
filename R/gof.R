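#' Mean weighted absolute deviation from a fitted quantile curve
#'
#' \eqn{V(\tau) = n^{-1} \sum_i w_i |y_i - q_i|} with weight `tau` when
#' `y_i >= q_i` and `1 - tau` otherwise; identical to the mean check loss
#' \eqn{n^{-1} \sum_i \rho_\tau(y_i - q_i)}.  Ties `y_i = q_i` fall in the
#' tau-weighted branch (and contribute zero either way).
#'
#' @param y observed responses.
#' @param q_at_x fitted conditional quantiles at the same covariate points.
#' @param tau quantile level in (0, 1).
#' @return nonnegative scalar.
#' @export
weighted_loss <- function(y, q_at_x, tau) {
  check_tau(tau)
  if (length(y) != length(q_at_x) || length(y) < 1L)
    qr_error("qr_invalid_input", "y and q_at_x must have equal positive length")
  mean(check_loss(y - q_at_x, tau))
}

#' Relative goodness-of-fit index between two quantile fits
#'
#' \eqn{R(\tau) = 1 - V_D(\tau)/V_R(\tau)}, where \eqn{V_D} and \eqn{V_R}
#' are the mean weighted absolute deviations of the data from the direct
#' and reference (linear) fitted quantiles.  Positive values favor the
#' direct fit.  Values below -1 are arithmetically possible (when
#' \eqn{V_D > 2 V_R}); they are reported as-is with a warning rather than
#' clipped.
#'
#' @param sample a [regression_sample()] (or a numeric response vector).
#' @param fitted_direct fitted values of the direct estimator at the sample
#'   covariates.
#' @param fitted_reference fitted values of the reference estimator at the
#'   sample covariates.
#' @param tau quantile level in (0, 1).
#' @return object of class `gof_report`: `tau`, `V_D`, `V_R`,
#'   `relative_R`, `in_range`.
#' @export
relative_R <- function(sample, fitted_direct, fitted_reference, tau) {
  y <- if (inherits(sample, "regression_sample")) sample$y else sample
  V_D <- weighted_loss(y, fitted_direct, tau)
  V_R <- weighted_loss(y, fitted_reference, tau)
  if (V_R == 0)
    qr_error("qr_perfect_reference",
             "reference fit interpolates the data (V_R = 0); R is undefined")
  R <- 1 - V_D / V_R
  in_range <- R >= -1 && R <= 1
  if (!in_range)
    qr_warn("qr_gof_out_of_range",
            sprintf("relative R = %.4f lies outside [-1, 1]", R))
  structure(list(tau = tau, V_D = V_D, V_R = V_R, relative_R = R,
                 in_range = in_range),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("<gof_report> tau = %g  V_D = %.6g  V_R = %.6g  R = %.4f%s\n",
              x$tau, x$V_D, x$V_R, x$relative_R,
              if (x$in_range) "" else "  [outside [-1,1]]"))
  invisible(x)
}
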