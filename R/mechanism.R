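#' Minimum size to initiate secondary nucleation
#'
#' Under the single-nucleus mechanism the induction-time offset at each
#' supersaturation is the time for one nucleus to grow to the minimum size
#' L_sn that triggers detectable secondary nucleation: offset = L_sn / G(S).
#' Fitting offset versus 1/G with a least-squares line through the origin
#' therefore gives L_sn as the slope (units um).
#'
#' @param inv_G Inverse growth rates, min/um (> 0), one per supersaturation,
#'   evaluated from the fitted growth power law.
#' @param offset Induction-time offsets, min (> 0): either the minimum
#'   induction time recorded or the fitted growth time t_g.
#' @return List with `L_sn_um` (the through-origin slope), `se` and
#'   `n_points`.
#' @export
offset_fit_through_origin <- function(inv_G, offset) {
  if (length(inv_G) != length(offset)) {
    stop_crystkin("inv_G and offset lengths differ",
                  "crystkin_invalid_argument")
  }
  if (length(inv_G) < 2L) {
    stop_crystkin("need >= 2 offset points", "crystkin_insufficient_data")
  }
  check_positive(inv_G, "inv_G")
  check_positive(offset, "offset")
  fit <- stats::lm(offset ~ inv_G - 1)
  list(L_sn_um = unname(coef(fit)[[1L]]),
       se = unname(suppressWarnings(summary(fit))$coefficients[1L, 2L]),
       n_points = length(inv_G))
}

#' Minimum delay and detectable size from seeded delay times
#'
#' Mean seeded delay times plotted against 1/G(S) follow a line whose
#' intercept is the minimum delay for secondary nucleation to start after
#' seed addition (min) and whose slope is the size secondary nuclei must
#' reach to be detected (um). Ordinary least squares with a free intercept.
#'
#' @param inv_G Inverse growth rates, min/um (>= 3 points).
#' @param mean_delay Mean delay times, min, one per supersaturation.
#' @return List with `t_min_delay_min` (intercept), `L_det_um` (slope),
#'   their standard errors and `r_squared`.
#' @export
delay_fit_free_intercept <- function(inv_G, mean_delay) {
  if (length(inv_G) != length(mean_delay)) {
    stop_crystkin("inv_G and mean_delay lengths differ",
                  "crystkin_invalid_argument")
  }
  if (length(inv_G) < 3L) {
    stop_crystkin("need >= 3 delay points", "crystkin_insufficient_data")
  }
  f <- ols_slope_fit(inv_G, mean_delay)
  list(t_min_delay_min = f$intercept, L_det_um = f$slope,
       intercept_se = unname(suppressWarnings(summary(stats::lm(mean_delay ~ inv_G)))$coefficients[1L, 2L]),
       slope_se = f$se, r_squared = f$r_squared)
}

#' Theoretical growth time to reach the minimum secondary-nucleation size
#'
#' t_g(S) = L_sn / G(S), with G from the fitted growth power law; the curve
#' traced under the induction-time scatter when offsets are plotted against
#' supersaturation.
#'
#' @param L_sn_um Minimum secondary-nucleation size, um (> 0).
#' @param growth_fit A growth `power_law_fit` (um/min).
#' @param S Supersaturations (> 1).
#' @return Growth times, min; strictly decreasing in S.
#' @export
predicted_growth_time <- function(L_sn_um, growth_fit, S) {
  check_positive(L_sn_um, "L_sn_um")
  L_sn_um / evaluate_power_law(growth_fit, S)
}

#' Crystallization behavior assessment table
#'
#' Aligns primary nucleation, secondary nucleation and growth rate estimates
#' on their shared supersaturations: per S, the growth rate from the fitted
#' power law, the seeded secondary nucleation rate per single seed crystal
#' per vial, and the primary nucleation rate per vial (J x V). In this
#' system secondary rates exceed primary rates by several orders of
#' magnitude, which is what licenses the single-nucleus reading of unseeded
#' experiments.
#'
#' @param induction_fits List of `induction_fit` objects (each with its `S`).
#' @param secondary_rates List of B `rate_estimate` objects (each with `S`).
#' @param growth_fit A growth `power_law_fit`.
#' @return Data frame with columns `S`, `G_um_min`, `B_per_mL_min`
#'   (NA where absent), `JV_per_min` (NA where absent), sorted by S.
#' @export
behavior_table <- function(induction_fits = list(),
                           secondary_rates = list(),
                           growth_fit) {
  stopifnot(inherits(growth_fit, "power_law_fit"))
  if (length(induction_fits) == 0L && length(secondary_rates) == 0L) {
    stop_crystkin("no rate estimates supplied", "crystkin_insufficient_data")
  }
  S_J <- vapply(induction_fits, function(f) f$S, numeric(1))
  S_B <- vapply(secondary_rates, function(r) r$S, numeric(1))
  S_all <- sort(unique(c(S_J, S_B)))
  S_all <- S_all[is.finite(S_all)]
  if (length(S_all) == 0L) {
    stop_crystkin("no supersaturation metadata on the estimates",
                  "crystkin_insufficient_data")
  }
  tab <- data.frame(S = S_all, G_um_min = evaluate_power_law(growth_fit, S_all),
                    B_per_mL_min = NA_real_, JV_per_min = NA_real_)
  for (f in induction_fits) {
    i <- match(f$S, tab$S)
    tab$JV_per_min[i] <- f$J * f$V
  }
  # average replicate seeded vials at the same supersaturation
  for (s in unique(S_B)) {
    vals <- vapply(secondary_rates[S_B == s], function(r) r$value, numeric(1))
    tab$B_per_mL_min[match(s, tab$S)] <- mean(vals)
  }
  tab
}
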