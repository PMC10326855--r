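#' A censored ensemble of isothermal induction times
#'
#' One unseeded induction-time campaign at a fixed supersaturation: per vial,
#' either the observed induction time (minutes from reaching isothermal
#' conditions to detection) or a censoring flag when no nucleation was seen
#' within the hold.
#'
#' @param time_min Times, min; for censored vials the value is the censoring
#'   time and is ignored by the estimators beyond counting.
#' @param nucleated Logical (or 0/1) vector: was nucleation detected?
#' @param volume_mL Vial solution volume, mL.
#' @param censor_time Isothermal hold, min.
#' @param S Supersaturation (optional metadata).
#' @param vial_id Optional identifiers.
#' @return An object of class `induction_dataset`.
#' @export
induction_dataset <- function(time_min, nucleated, volume_mL = 3,
                              censor_time = 240, S = NA_real_,
                              vial_id = seq_along(time_min)) {
  nucleated <- as.logical(nucleated)
  if (length(time_min) != length(nucleated)) {
    stop_crystkin("time_min and nucleated lengths differ",
                  "crystkin_invalid_argument")
  }
  if (length(time_min) < 1L) {
    stop_crystkin("empty induction dataset", "crystkin_insufficient_data")
  }
  obs <- time_min[nucleated]
  if (any(obs <= 0) || any(obs > censor_time + sqrt(.Machine$double.eps))) {
    stop_crystkin("observed induction times must lie in (0, censor_time]",
                  "crystkin_invalid_argument")
  }
  check_positive(volume_mL, "volume_mL")
  structure(
    list(data = data.frame(vial_id = vial_id, time_min = time_min,
                           nucleated = nucleated),
         volume = volume_mL, censor_time = censor_time, S = S),
    class = "induction_dataset"
  )
}

#' @export
print.induction_dataset <- function(x, ...) {
  cat(sprintf("induction ensemble: M = %d vials (%d nucleated), V = %g mL, censor = %g min\n",
              nrow(x$data), sum(x$data$nucleated), x$volume, x$censor_time))
  invisible(x)
}

#' Empirical cumulative distribution of induction times
#'
#' P(t) = M+(t) / M, where M+ is the number of vials in which nucleation was
#' detected at a time less than or equal to t and M is the full ensemble size
#' including censored vials. Ties are merged into a single step.
#'
#' @param dataset An [induction_dataset()].
#' @return Data frame with columns `time_min` (sorted unique observed times)
#'   and `P` (non-decreasing, in \[0, 1\]); zero rows if every vial is
#'   censored.
#' @export
empirical_cdf <- function(dataset) {
  stopifnot(inherits(dataset, "induction_dataset"))
  M <- nrow(dataset$data)
  obs <- sort(dataset$data$time_min[dataset$data$nucleated])
  if (length(obs) == 0L) {
    return(data.frame(time_min = numeric(0), P = numeric(0)))
  }
  t_unique <- unique(obs)
  data.frame(
    time_min = t_unique,
    P = vapply(t_unique, function(t) sum(obs <= t), numeric(1)) / M
  )
}

#' Model cumulative probability of induction times
#'
#' Under the single-nucleus mechanism, the nucleation waiting time is
#' exponential with rate J*V and detection lags by a deterministic growth
#' time t_g, so P(t) = 1 - exp(-J V (t - t_g)) for t > t_g and 0 otherwise.
#'
#' @param J Primary nucleation rate, nuclei/(mL min) (>= 0).
#' @param V Volume, mL (>= 0).
#' @param t_g Growth-time offset, min (>= 0).
#' @param t Times, min (>= 0).
#' @return Probabilities in \[0, 1\].
#' @export
induction_probability <- function(J, V, t_g, t) {
  if (any(t < 0)) {
    stop_crystkin("t must be non-negative", "crystkin_invalid_argument")
  }
  stopifnot(J >= 0, V >= 0, t_g >= 0)
  ifelse(t <= t_g, 0, 1 - exp(-J * V * (t - t_g)))
}

#' Minimum induction time of an ensemble
#'
#' The smallest observed induction time; an empirical proxy for the
#' growth-time offset, since no vial can be detected before its single
#' nucleus has grown to the detectable-secondary-nucleation size.
#'
#' @param dataset An [induction_dataset()].
#' @return Minimum observed induction time, min.
#' @export
minimum_induction_time <- function(dataset) {
  stopifnot(inherits(dataset, "induction_dataset"))
  obs <- dataset$data$time_min[dataset$data$nucleated]
  if (length(obs) == 0L) {
    stop_crystkin("no nucleated vials: minimum induction time undefined",
                  "crystkin_insufficient_data")
  }
  min(obs)
}

#' Fit the primary nucleation rate and growth-time offset
#'
#' Nonlinear least squares of the exponential induction-time model against
#' the empirical CDF, with parameters (J, t_g) constrained non-negative and
#' solved by the Levenberg-Marquardt algorithm. Censored vials enter only
#' through the CDF denominator M. Initialisation is data-driven
#' (t_g0 = minimum induction time, J0 from the last CDF point); on failure
#' the fit restarts from jittered starts.
#'
#' @param dataset An [induction_dataset()].
#' @param min_nucleated Minimum number of nucleated vials required (default 5).
#' @return An object of class `induction_fit`: `J` and `t_g` with standard
#'   errors (`J_se`, `t_g_se`), `V`, `M`, `n_nucleated`, `residual_norm`, the
#'   CDF points used (`cdf`) and the `nls` object (`fit`).
#' @export
fit_induction_model <- function(dataset, min_nucleated = 5L) {
  stopifnot(inherits(dataset, "induction_dataset"))
  cdf <- empirical_cdf(dataset)
  n_nuc <- sum(dataset$data$nucleated)
  if (n_nuc < min_nucleated) {
    stop_crystkin(sprintf("only %d nucleated vials; >= %d required",
                          n_nuc, min_nucleated),
                  "crystkin_insufficient_data")
  }
  V <- dataset$volume
  mit <- min(cdf$time_min)
  P_max <- max(cdf$P)
  t_last <- max(cdf$time_min)
  J0 <- if (P_max < 1 && t_last > mit) {
    log(1 / (1 - P_max)) / (V * (t_last - mit))
  } else {
    1 / (V * max(t_last - mit, 1))
  }
  starts <- list(c(J = J0, t_g = mit))
  # deterministic jittered restarts used only on non-convergence
  for (f in c(0.5, 2, 0.2, 5)) {
    starts <- c(starts, list(c(J = J0 * f, t_g = mit * min(1, 1 / f))))
  }
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        P ~ induction_probability(J, V, t_g, time_min),
        data = cdf,
        start = as.list(st),
        lower = c(J = 0, t_g = 0),
        upper = c(J = Inf, t_g = mit),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop_crystkin("induction-time fit failed to converge from all starts",
                  "crystkin_fit_failure")
  }
  est <- coef(fit)
  # polish on the same least-squares objective with parameter scaling;
  # LM can declare convergence on the shallow (J, t_g) correlation valley
  ssr <- function(p) {
    sum((cdf$P - induction_probability(p[1L], V, p[2L], cdf$time_min))^2)
  }
  pol <- tryCatch(
    stats::nlminb(est, ssr, lower = c(0, 0), upper = c(Inf, mit),
                  scale = 1 / pmax(abs(est), c(1e-8, 1e-3)),
                  control = list(rel.tol = 1e-15, iter.max = 500L)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$objective <= ssr(est)) {
    est <- stats::setNames(pol$par, c("J", "t_g"))
  }
  se <- induction_fit_se(est, V, cdf)
  structure(
    list(J = unname(est[["J"]]), J_se = unname(se[["J"]]),
         t_g = unname(est[["t_g"]]), t_g_se = unname(se[["t_g"]]),
         V = V, M = nrow(dataset$data), n_nucleated = n_nuc,
         residual_norm = sqrt(ssr(est)),
         cdf = cdf, S = dataset$S, fit = fit),
    class = "induction_fit"
  )
}

# standard errors from the numeric Jacobian of the model at the optimum
induction_fit_se <- function(est, V, cdf) {
  n <- nrow(cdf)
  if (n <= 2L) return(c(J = NA_real_, t_g = NA_real_))
  h <- pmax(abs(est), c(1e-8, 1e-3)) * 1e-6
  jac <- vapply(1:2, function(k) {
    up <- dn <- est
    up[k] <- est[k] + h[k]
    dn[k] <- max(est[k] - h[k], 0)
    (induction_probability(up[1L], V, up[2L], cdf$time_min) -
       induction_probability(dn[1L], V, dn[2L], cdf$time_min)) /
      (up[k] - dn[k])
  }, numeric(n))
  res <- cdf$P - induction_probability(est[1L], V, est[2L], cdf$time_min)
  sigma2 <- sum(res^2) / (n - 2L)
  cov <- tryCatch(sigma2 * solve(crossprod(jac)),
                  error = function(e) matrix(NA_real_, 2, 2))
  c(J = sqrt(cov[1L, 1L]), t_g = sqrt(cov[2L, 2L]))
}

#' @export
print.induction_fit <- function(x, ...) {
  cat(sprintf("induction-time fit (M = %d, nucleated = %d, V = %g mL)\n",
              x$M, x$n_nucleated, x$V))
  cat(sprintf("  J   = %.4g +/- %.2g nuclei/(mL min)\n", x$J, x$J_se))
  cat(sprintf("  t_g = %.4g +/- %.2g min\n", x$t_g, x$t_g_se))
  invisible(x)
}

#' Censored-exponential maximum likelihood cross-check
#'
#' Optional cross-check of the least-squares CDF fit: with t_g fixed, the
#' censored exponential MLE for the rate is J V = m / sum(t_i - t_g), where
#' the sum runs over observed waiting times plus censored exposures. Profiled
#' over t_g on a grid below the minimum induction time.
#'
#' @param dataset An [induction_dataset()].
#' @param t_g_grid Offsets to profile over; defaults to a grid from 0 to the
#'   minimum induction time.
#' @return List with `J`, `t_g` (profile maximiser), `loglik`.
#' @export
fit_induction_mle <- function(dataset, t_g_grid = NULL) {
  stopifnot(inherits(dataset, "induction_dataset"))
  obs <- dataset$data$time_min[dataset$data$nucleated]
  if (length(obs) == 0L) {
    stop_crystkin("no nucleated vials", "crystkin_insufficient_data")
  }
  n_cens <- sum(!dataset$data$nucleated)
  V <- dataset$volume
  if (is.null(t_g_grid)) {
    t_g_grid <- seq(0, min(obs) * 0.999, length.out = 200L)
  }
  ll <- vapply(t_g_grid, function(tg) {
    expo <- sum(obs - tg) + n_cens * (dataset$censor_time - tg)
    rate <- length(obs) / expo
    length(obs) * log(rate) - rate * expo
  }, numeric(1))
  best <- which.max(ll)
  tg <- t_g_grid[best]
  expo <- sum(obs - tg) + n_cens * (dataset$censor_time - tg)
  list(J = length(obs) / expo / V, t_g = tg, loglik = ll[best])
}
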