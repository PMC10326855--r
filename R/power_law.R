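#' Fit a power law in supersaturation, rate = k (S - 1)^n
#'
#' Crystal growth and secondary nucleation rates both tend to follow power
#' laws in the relative supersaturation S - 1. The fit is ordinary least
#' squares of ln(rate) against ln(S - 1) -- the reading of a straight line on
#' a log-log plot -- giving k = exp(intercept) and n = slope.
#'
#' @param S Supersaturation ratios (> 1).
#' @param rate Rates (> 0), in the units of the quantity being fitted
#'   (um/min for growth, particles/(mL min) for nucleation).
#' @param rate_kind One of `"growth"`, `"secondary_nucleation"`,
#'   `"primary_nucleation"`; carried as metadata.
#' @return An object of class `power_law_fit` with fields `k` (rate at
#'   S - 1 = 1), `n` (dimensionless exponent), `rate_kind`, `r_squared`
#'   (log space), `n_points`, and the underlying `fit`.
#' @examples
#' S <- 1 + c(0.04, 0.08, 0.13, 0.18)
#' fit <- fit_power_law(S, 3400 * (S - 1)^2.86, "growth")
#' fit$n   # 2.86
#' @export
fit_power_law <- function(S, rate,
                          rate_kind = c("growth", "secondary_nucleation",
                                        "primary_nucleation")) {
  rate_kind <- match.arg(rate_kind)
  if (length(S) != length(rate)) {
    stop_crystkin("S and rate lengths differ", "crystkin_invalid_argument")
  }
  if (length(S) < 2L) {
    stop_crystkin("need >= 2 points for a power-law fit",
                  "crystkin_insufficient_data")
  }
  if (any(!is.finite(S)) || any(S <= 1)) {
    stop_crystkin("all S must be finite and > 1", "crystkin_invalid_argument")
  }
  check_positive(rate, "rate")
  x <- log(S - 1)
  y <- log(rate)
  fit <- stats::lm(y ~ x)
  structure(
    list(
      k = exp(unname(coef(fit)[[1L]])),
      n = unname(coef(fit)[[2L]]),
      rate_kind = rate_kind,
      r_squared = suppressWarnings(summary(fit))$r.squared,
      n_points = length(S),
      fit = fit
    ),
    class = "power_law_fit"
  )
}

#' Evaluate a power-law fit at given supersaturations
#'
#' @param fit A `power_law_fit`.
#' @param S Supersaturations (> 1).
#' @return rate = k (S - 1)^n, same units as the fitted rates.
#' @export
evaluate_power_law <- function(fit, S) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(!is.finite(S)) || any(S <= 1)) {
    stop_crystkin("all S must be finite and > 1", "crystkin_invalid_argument")
  }
  fit$k * (S - 1)^fit$n
}

#' Supersaturation required to reach a target rate
#'
#' Inverts rate = k (S - 1)^n: S = 1 + (rate / k)^(1/n). Used, for example,
#' to map a required steady-state growth rate to an operating supersaturation.
#'
#' @param fit A `power_law_fit`.
#' @param target_rate Target rate (> 0), same units as the fitted rates.
#' @return Supersaturation S > 1.
#' @export
invert_power_law <- function(fit, target_rate) {
  stopifnot(inherits(fit, "power_law_fit"))
  check_positive(target_rate, "target_rate")
  1 + (target_rate / fit$k)^(1 / fit$n)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit (%s): rate = %.6g * (S-1)^%.4g\n",
              x$rate_kind, x$k, x$n))
  cat(sprintf("  n points = %d, R^2 (log space) = %.4f\n",
              x$n_points, x$r_squared))
  invisible(x)
}
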