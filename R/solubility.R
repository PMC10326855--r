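#' Solution supersaturation ratio
#'
#' Supersaturation is expressed as the concentration ratio S = C / C_s, the
#' driving-force convention used throughout the package. Both arguments are in
#' solute mass per solvent mass (mg per g of water).
#'
#' @param concentration Solution concentration, mg/g water.
#' @param solubility_ref Equilibrium solubility at the working temperature,
#'   mg/g water. Defaults to the alpha-glycine literature value at 25 C.
#' @return Dimensionless supersaturation ratio.
#' @examples
#' supersaturation(294.43)        # S = 1.18 for glycine at 25 C
#' supersaturation(300, 250)      # S = 1.2
#' @export
supersaturation <- function(concentration, solubility_ref = 249.52) {
  check_positive(concentration, "concentration")
  check_positive(solubility_ref, "solubility_ref")
  concentration / solubility_ref
}

#' Extrapolate clear-point temperatures to zero heating rate
#'
#' Clear points measured during heating ramps overestimate the equilibrium
#' solubility temperature because dissolution lags the ramp. An ordinary
#' least-squares line of clear point versus heating rate is extrapolated to a
#' zero heating rate; its intercept estimates the solubility temperature.
#'
#' @param heating_rate Heating rates, degrees C per min (> 0, at least two
#'   distinct values).
#' @param clear_point Clear-point temperatures, degrees C, same length.
#' @param level Confidence level for the intercept interval.
#' @return A list with `temperature` (degC), `se`, `conf_int` (length-2), the
#'   fitted `slope` (degC per (degC/min)) and the underlying `fit`.
#' @export
extrapolate_clear_point <- function(heating_rate, clear_point, level = 0.95) {
  check_positive(heating_rate, "heating_rate")
  if (length(heating_rate) != length(clear_point)) {
    stop_crystkin("heating_rate and clear_point lengths differ",
                  "crystkin_invalid_argument")
  }
  if (length(unique(heating_rate)) < 2L) {
    stop_crystkin("need >= 2 distinct heating rates to extrapolate",
                  "crystkin_insufficient_data")
  }
  fit <- stats::lm(clear_point ~ heating_rate)
  # noise-free calibration data legitimately yields a perfect fit
  sm <- suppressWarnings(summary(fit))$coefficients
  intercept <- sm["(Intercept)", "Estimate"]
  se <- sm["(Intercept)", "Std. Error"]
  df <- fit$df.residual
  half <- if (df > 0) stats::qt(1 - (1 - level) / 2, df) * se else NA_real_
  list(
    temperature = unname(intercept),
    se = unname(se),
    conf_int = unname(intercept + c(-1, 1) * half),
    slope = unname(coef(fit)[["heating_rate"]]),
    fit = fit
  )
}

#' Fit a van't Hoff solubility model
#'
#' Fits ln(C) = a - b / T(K) by ordinary least squares, the usual linearised
#' van't Hoff representation of temperature-dependent solubility. The fit is
#' on mass concentration (mg/g water); only relative trends are consumed
#' downstream, so the composition basis does not affect derived kinetics.
#'
#' @param temperature_C Temperatures, degrees C (distinct, >= 2 points).
#' @param solubility Solubilities, mg/g water (> 0).
#' @return An object of class `solubility_model` with fields `intercept` (a,
#'   dimensionless), `slope_K` (b, kelvin; positive when solubility increases
#'   with temperature), `range_C`, and `fit`.
#' @seealso [predict.solubility_model()]
#' @export
fit_vant_hoff <- function(temperature_C, solubility) {
  check_positive(solubility, "solubility")
  if (length(temperature_C) != length(solubility)) {
    stop_crystkin("temperature_C and solubility lengths differ",
                  "crystkin_invalid_argument")
  }
  if (length(unique(temperature_C)) < 2L) {
    stop_crystkin("need >= 2 distinct temperatures for a van't Hoff fit",
                  "crystkin_insufficient_data")
  }
  inv_T <- 1 / (temperature_C + 273.15)
  fit <- stats::lm(log(solubility) ~ inv_T)
  structure(
    list(
      intercept = unname(coef(fit)[[1L]]),
      slope_K = -unname(coef(fit)[[2L]]),
      range_C = range(temperature_C),
      fit = fit
    ),
    class = "solubility_model"
  )
}

#' Predict solubility from a van't Hoff model
#'
#' @param object A `solubility_model`.
#' @param temperature_C Temperatures, degrees C.
#' @param ... Unused.
#' @return Predicted solubility, mg/g water.
#' @export
predict.solubility_model <- function(object, temperature_C, ...) {
  exp(object$intercept - object$slope_K / (temperature_C + 273.15))
}

#' @export
print.solubility_model <- function(x, ...) {
  cat("van't Hoff solubility model: ln C =",
      format(x$intercept, digits = 6), "-",
      format(x$slope_K, digits = 6), "/ T(K)\n")
  cat("fitted over", format(x$range_C[1]), "to", format(x$range_C[2]), "degC\n")
  invisible(x)
}
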