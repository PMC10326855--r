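#' Simulation configuration for synthetic instrument datasets
#'
#' Bundles the ground-truth kinetic parameters and detection geometry used by
#' the Monte-Carlo simulators. Defaults reflect the study conditions the
#' estimators are designed for: 3 mL agitated vials held isothermally with a
#' 4 h censoring window, imaging detection over 99 linear size bins spanning
#' 3-300 um, a reliable count window of 10-160 particles per image, and a
#' linear count-to-density calibration.
#'
#' @param J_true Primary nucleation rate, nuclei/(mL min).
#' @param V Vial solution volume, mL.
#' @param t_g_true Growth-time offset between nucleation and detection, min.
#' @param censor_time Isothermal hold, min; vials not nucleated by then are
#'   censored.
#' @param B_true Secondary nucleation rate, particles/(mL min).
#' @param delay_true Seeded detection delay, min.
#' @param G_true Crystal growth rate, um/min.
#' @param calibration_factor (particles/mL) per (count/image); the simulator
#'   and the estimators must share this value.
#' @param initial_size_um Birth size of secondary nuclei, um; below the 3 um
#'   detection floor since the true birth size is unobservable.
#' @param time_step Frame interval, min.
#' @param seed Integer seed; every simulator is bit-reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(J_true = 1.3e-3, V = 3, t_g_true = 37,
                       censor_time = 240, B_true = 5000, delay_true = 5,
                       G_true = 10, calibration_factor = 100,
                       initial_size_um = 1, time_step = 1, seed = 1L) {
  stopifnot(J_true >= 0, B_true >= 0, G_true >= 0, delay_true >= 0,
            t_g_true >= 0)
  check_positive(V, "V")
  check_positive(censor_time, "censor_time")
  check_positive(calibration_factor, "calibration_factor")
  check_positive(time_step, "time_step")
  structure(
    list(J_true = J_true, V = V, t_g_true = t_g_true,
         censor_time = censor_time, B_true = B_true,
         delay_true = delay_true, G_true = G_true,
         calibration_factor = calibration_factor,
         initial_size_um = initial_size_um,
         time_step = time_step, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Size-bin edges of the imaging detector
#'
#' 99 linear bins spanning 3 to 300 um (bin width 3 um).
#'
#' @return Numeric vector of 100 strictly increasing edges.
#' @export
psd_bin_edges <- function() {
  seq(3, 300, length.out = 100L)
}

#' Simulate a censored induction-time ensemble
#'
#' Each vial nucleates after an exponential waiting time with rate J*V
#' (a constant-rate Poisson process with at most one recorded event per
#' vial), and the event is detected a deterministic growth time t_g later.
#' Induction times exceeding the censoring window are recorded as censored.
#' With `stochastic = FALSE` the waiting times are placed at the exponential
#' quantiles i/n (the top quantiles fall beyond the censoring window and are
#' censored), so the empirical CDF of the ensemble lies exactly on the model
#' curve; useful for noise-free inversion checks.
#'
#' @param config A [sim_config()].
#' @param n_vials Number of vials (>= 1).
#' @param stochastic Draw waiting times randomly (default) or at exponential
#'   quantiles.
#' @return An [induction_dataset()].
#' @export
simulate_induction_times <- function(config, n_vials, stochastic = TRUE) {
  stopifnot(inherits(config, "sim_config"), n_vials >= 1)
  rate <- config$J_true * config$V
  if (rate == 0) {
    wait <- rep(Inf, n_vials)
  } else if (stochastic) {
    set.seed(config$seed)
    wait <- stats::rexp(n_vials, rate = rate)
  } else {
    wait <- stats::qexp(seq_len(n_vials) / n_vials, rate = rate)
  }
  t_ind <- wait + config$t_g_true
  nucleated <- t_ind <= config$censor_time
  induction_dataset(
    time_min = ifelse(nucleated, t_ind, config$censor_time),
    nucleated = nucleated,
    volume_mL = config$V,
    censor_time = config$censor_time
  )
}

#' Simulate a seeded particle-count trace
#'
#' After a detection delay following seed addition at t = 0, the particle
#' number density rises linearly at the secondary nucleation rate B. The
#' density is converted to counts per image through the calibration factor;
#' in stochastic mode each frame count is a Poisson draw around the expected
#' count, in deterministic mode the expectation itself is returned (then
#' exactly linear after the delay, but not necessarily integer).
#'
#' @param config A [sim_config()].
#' @param duration Trace length, min (> delay).
#' @param stochastic Poisson frame noise (default) or exact expectations.
#' @return A [count_series()].
#' @export
simulate_seeded_counts <- function(config, duration, stochastic = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (duration <= config$delay_true) {
    stop_crystkin("duration must exceed the detection delay",
                  "crystkin_invalid_argument")
  }
  times <- seq(0, duration, by = config$time_step)
  density <- config$B_true * pmax(times - config$delay_true, 0)
  expected <- density / config$calibration_factor
  if (stochastic) {
    set.seed(config$seed)
    counts <- stats::rpois(length(times), lambda = expected)
  } else {
    counts <- expected
  }
  count_series(time_min = times, count = counts,
               calibration_factor = config$calibration_factor)
}

#' Simulate a time series of number-weighted size histograms
#'
#' New particles appear by secondary nucleation at rate B*V (Poisson counts
#' per frame interval; exact expectations with carry in deterministic mode)
#' at a birth size below the 3 um detection floor, and every particle grows
#' at the single prevailing rate G. Each frame histograms the current sizes
#' into the 99 linear detector bins, ignoring particles outside 3-300 um.
#'
#' @param config A [sim_config()].
#' @param duration Series length, min (> 0).
#' @param stochastic Poisson birth counts (default) or deterministic ones.
#' @return A [psd_series()].
#' @export
simulate_psd_series <- function(config, duration, stochastic = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  check_positive(duration, "duration")
  dt <- config$time_step
  step_starts <- seq(0, duration - dt, by = dt)
  lambda <- config$B_true * config$V * dt
  if (stochastic) {
    set.seed(config$seed)
    births_per_step <- stats::rpois(length(step_starts), lambda)
    birth_times <- rep(step_starts, births_per_step) +
      stats::runif(sum(births_per_step), 0, dt)
  } else {
    # carry fractional expectations so births up to time t track B*V*t
    cum <- floor(lambda * seq_along(step_starts))
    births_per_step <- diff(c(0, cum))
    birth_times <- rep(step_starts + dt, births_per_step)
  }
  frame_times <- seq(dt, duration, by = dt)
  edges <- psd_bin_edges()
  counts <- matrix(0L, nrow = length(frame_times), ncol = 99L)
  for (i in seq_along(frame_times)) {
    t <- frame_times[i]
    alive <- birth_times <= t
    if (!any(alive)) next
    sizes <- config$initial_size_um + config$G_true * (t - birth_times[alive])
    visible <- sizes >= edges[1L] & sizes <= edges[100L]
    if (!any(visible)) next
    h <- findInterval(sizes[visible], edges, rightmost.closed = TRUE)
    counts[i, ] <- tabulate(h, nbins = 99L)
  }
  psd_series(time_min = frame_times, counts = counts,
             n_births = length(birth_times))
}

#' Simulate a full kinetic-assessment campaign
#'
#' For each supersaturation, the primary nucleation rate J, secondary
#' nucleation rate B and growth rate G are set from the supplied power laws,
#' the growth-time offset is constructed as t_g = L_sn / G(S) (the time for a
#' single nucleus to reach the minimum size initiating detectable secondary
#' nucleation), and the seeded delay as delay = t_min + L_det / G(S). One
#' induction ensemble, `n_traces` seeded count traces and one PSD series are
#' emitted per supersaturation, with the generating truth embedded for test
#' harnesses.
#'
#' @param S_values Supersaturations (> 1, non-empty).
#' @param config Base [sim_config()]; per-condition rates override its truth
#'   fields, per-condition seeds are derived from `config$seed`.
#' @param growth_law,secondary_law,primary_law Lists `list(k =, n =)` giving
#'   prefactor and exponent of each power law (units: um/min, particles/(mL
#'   min), nuclei/(mL min) at S - 1 = 1).
#' @param L_sn_um Minimum secondary-nucleation size, um.
#' @param delay_min_min Minimum seeded delay, min.
#' @param L_det_um Detectable size of secondary nuclei, um.
#' @param n_vials Induction vials per supersaturation.
#' @param n_traces Seeded count traces per supersaturation.
#' @param stochastic Passed through to the individual simulators.
#' @return A list of class `workflow_suite`: per-S `conditions` (data frame
#'   of truth values), `induction` (list of datasets), `counts` (list of
#'   lists of count series), `psd` (list of PSD series).
#' @export
simulate_workflow_suite <- function(S_values, config = sim_config(),
                                    growth_law = list(k = 3400, n = 2.86),
                                    secondary_law = list(k = 6e6, n = 3.5),
                                    primary_law = list(k = 7, n = 3.4),
                                    L_sn_um = 150, delay_min_min = 5,
                                    L_det_um = 9,
                                    n_vials = 25, n_traces = 3,
                                    stochastic = TRUE) {
  if (length(S_values) == 0L) {
    stop_crystkin("S_values must be non-empty", "crystkin_invalid_argument")
  }
  if (any(S_values <= 1)) {
    stop_crystkin("all S_values must be > 1", "crystkin_invalid_argument")
  }
  pl <- function(law, S) law$k * (S - 1)^law$n
  conditions <- data.frame(
    S = S_values,
    J = pl(primary_law, S_values),
    B = pl(secondary_law, S_values),
    G = pl(growth_law, S_values)
  )
  conditions$t_g <- L_sn_um / conditions$G
  conditions$delay <- delay_min_min + L_det_um / conditions$G

  induction <- vector("list", length(S_values))
  counts <- vector("list", length(S_values))
  psd <- vector("list", length(S_values))
  for (i in seq_along(S_values)) {
    row <- conditions[i, ]
    cfg_i <- config
    cfg_i$J_true <- row$J
    cfg_i$B_true <- row$B
    cfg_i$G_true <- row$G
    cfg_i$t_g_true <- row$t_g
    cfg_i$delay_true <- row$delay
    cfg_i$seed <- config$seed + 1000L * i
    induction[[i]] <- simulate_induction_times(cfg_i, n_vials, stochastic)
    induction[[i]]$S <- row$S
    # frame interval resolving the 10-160 count window into >= 10 frames,
    # trace long enough to sweep past the window ceiling
    span <- 150 * cfg_i$calibration_factor / row$B
    dt_counts <- min(config$time_step, span / 10)
    dur_counts <- row$delay + span * 1.5 + 5 * dt_counts
    counts[[i]] <- lapply(seq_len(n_traces), function(j) {
      cfg_j <- cfg_i
      cfg_j$seed <- cfg_i$seed + j
      cfg_j$time_step <- dt_counts
      cs <- simulate_seeded_counts(cfg_j, duration = dur_counts, stochastic)
      cs$S <- row$S
      cs
    })
    # long enough for a d90 trend, short enough that the earliest particles
    # stay below the 300 um detection ceiling
    dur_psd <- min(280 / row$G, max(30 / row$G, 20 * cfg_i$time_step))
    cfg_p <- cfg_i
    cfg_p$seed <- cfg_i$seed + 500L
    cfg_p$time_step <- dur_psd / 25
    psd[[i]] <- simulate_psd_series(cfg_p, duration = dur_psd, stochastic)
    psd[[i]]$S <- row$S
  }
  structure(
    list(conditions = conditions, induction = induction, counts = counts,
         psd = psd,
         truth = list(growth_law = growth_law,
                      secondary_law = secondary_law,
                      primary_law = primary_law,
                      L_sn_um = L_sn_um, delay_min_min = delay_min_min,
                      L_det_um = L_det_um)),
    class = "workflow_suite"
  )
}
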