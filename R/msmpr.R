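# Steady-state MSMPR relations for cubic crystals.
#
# Population density n(L) = n0 exp(-L / (G tau)) implies, for volume shape
# factor k_v = 1 (cubes):
#   phi  = k_v * n0 * integral L^3 n(L)/n0 dL = 6 k_v n0 (G tau)^4
#   d43  = integral L^4 n dL / integral L^3 n dL = 4 G tau
#   B    = n0 * G
# All internal arithmetic is SI (m, s); public values use um/min and
# particles/(mL min).

KV_CUBIC <- 1

M_PER_UM <- 1e-6
ML_PER_M3 <- 1e6
S_PER_MIN <- 60

G_si_to_um_min <- function(G_m_s) G_m_s / M_PER_UM * S_PER_MIN
G_um_min_to_si <- function(G) G * M_PER_UM / S_PER_MIN
B_si_to_mL_min <- function(B_m3_s) B_m3_s / ML_PER_M3 * S_PER_MIN
B_mL_min_to_si <- function(B) B * ML_PER_M3 / S_PER_MIN

#' Nucleation and growth rates required for an MSMPR design point
#'
#' Solves the steady-state cubic-crystal MSMPR relations for the nucleation
#' rate B and growth rate G that deliver a target solids volume fraction phi,
#' volume-weighted mean size d43 and mean residence time tau:
#' G = d43 / (4 tau) and B = n0 G with n0 = phi / (6 k_v (G tau)^4).
#'
#' @param phi Solids volume fraction (dimensionless, > 0).
#' @param d43_m Volume-weighted mean crystal size, m (> 0).
#' @param tau_s Mean residence time, s (> 0).
#' @param k_v Volume shape factor (1 for cubes).
#' @return An object of class `msmpr_design` with `phi`, `d43_m`, `tau_s`,
#'   `G_um_min`, `B_per_mL_min` and the intermediate `n0_per_m4` (nuclei
#'   population density, 1/(m^3 m)).
#' @examples
#' msmpr_required_rates(0.1, 1e-4, 1000)  # B = 6.4e4 /(mL min), G = 1.5 um/min
#' @export
msmpr_required_rates <- function(phi, d43_m, tau_s, k_v = KV_CUBIC) {
  check_positive(phi, "phi")
  check_positive(d43_m, "d43_m")
  check_positive(tau_s, "tau_s")
  G <- d43_m / (4 * tau_s)            # m/s
  n0 <- phi / (6 * k_v * (G * tau_s)^4)
  B <- n0 * G                          # 1/(m^3 s)
  structure(
    list(phi = phi, d43_m = d43_m, tau_s = tau_s,
         G_um_min = G_si_to_um_min(G),
         B_per_mL_min = B_si_to_mL_min(B),
         n0_per_m4 = n0, k_v = k_v),
    class = "msmpr_design"
  )
}

#' MSMPR product attributes from nucleation and growth rates
#'
#' Inverse of [msmpr_required_rates()]: given the overall nucleation rate B,
#' growth rate G and residence time tau, returns the steady-state solids
#' volume fraction and volume-weighted mean size. Round-trips with the
#' forward map to floating-point accuracy.
#'
#' @param B_per_mL_min Overall nucleation rate, particles/(mL min) (> 0).
#' @param G_um_min Growth rate, um/min (> 0).
#' @param tau_s Residence time, s (> 0).
#' @param k_v Volume shape factor (1 for cubes).
#' @return List with `phi` and `d43_m`.
#' @export
msmpr_forward <- function(B_per_mL_min, G_um_min, tau_s, k_v = KV_CUBIC) {
  check_positive(B_per_mL_min, "B_per_mL_min")
  check_positive(G_um_min, "G_um_min")
  check_positive(tau_s, "tau_s")
  G <- G_um_min_to_si(G_um_min)
  B <- B_mL_min_to_si(B_per_mL_min)
  n0 <- B / G
  list(phi = 6 * k_v * n0 * (G * tau_s)^4,
       d43_m = 4 * G * tau_s)
}

#' @export
print.msmpr_design <- function(x, ...) {
  cat(sprintf("MSMPR design point (cubic crystals, k_v = %g)\n", x$k_v))
  cat(sprintf("  phi = %g, d43 = %g m, tau = %g s\n", x$phi, x$d43_m, x$tau_s))
  cat(sprintf("  required G = %.4g um/min\n", x$G_um_min))
  cat(sprintf("  required B = %.4g particles/(mL min)\n", x$B_per_mL_min))
  invisible(x)
}

#' Operating supersaturation for an MSMPR design point
#'
#' Maps the required growth rate of a design point to the supersaturation
#' that delivers it (inverting the growth power law) and evaluates the
#' secondary nucleation power law there, so the attainable B can be compared
#' with the required one. Note the experimental B is per single seed crystal
#' in a vial while the MSMPR B is per suspension volume; the comparison is an
#' order-of-magnitude feasibility check.
#'
#' @param design An `msmpr_design`.
#' @param growth_fit Growth `power_law_fit` (um/min).
#' @param secondary_fit Secondary-nucleation `power_law_fit`
#'   (particles/(mL min)).
#' @return List with `S_required`, `B_available_per_mL_min`,
#'   `B_required_per_mL_min` and `feasible` (B available within a factor of
#'   10 of required, or larger).
#' @export
operating_point <- function(design, growth_fit, secondary_fit) {
  stopifnot(inherits(design, "msmpr_design"))
  S_req <- invert_power_law(growth_fit, design$G_um_min)
  B_avail <- evaluate_power_law(secondary_fit, S_req)
  list(S_required = S_req,
       B_available_per_mL_min = B_avail,
       B_required_per_mL_min = design$B_per_mL_min,
       feasible = B_avail >= design$B_per_mL_min / 10)
}
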