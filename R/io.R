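# Plain-text table readers with row-level validation, plus the pipeline
# driver tying simulate -> fit -> analyze -> report together.

validate_or_stop <- function(failures) {
  if (length(failures)) {
    stop_crystkin(paste0("validation failed:\n  ",
                         paste(failures, collapse = "\n  ")),
                  "crystkin_validation_error")
  }
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_crystkin(sprintf("%s: missing column(s) %s", path,
                          paste(missing, collapse = ", ")),
                  "crystkin_validation_error")
  }
}

#' Read an induction-time table
#'
#' Expected columns: `vial_id`, `supersaturation`, `time_min`, `nucleated`
#' (0/1). Returns one [induction_dataset()] per supersaturation.
#'
#' @param path CSV path.
#' @param volume_mL Vial volume, mL.
#' @param censor_time Censoring time, min.
#' @return Named list of `induction_dataset` objects keyed by supersaturation.
#' @export
read_induction_csv <- function(path, volume_mL = 3, censor_time = 240) {
  df <- utils::read.csv(path)
  require_columns(df, c("vial_id", "supersaturation", "time_min", "nucleated"),
                  path)
  fails <- character(0)
  bad_t <- which(df$nucleated == 1 &
                   (df$time_min <= 0 | df$time_min > censor_time))
  if (length(bad_t)) {
    fails <- c(fails, sprintf("row %d: observed time_min outside (0, %g]",
                              bad_t, censor_time))
  }
  if (!all(df$nucleated %in% c(0, 1))) {
    fails <- c(fails, sprintf("row %d: nucleated must be 0/1",
                              which(!df$nucleated %in% c(0, 1))))
  }
  validate_or_stop(fails)
  by_S <- split(df, df$supersaturation)
  stats::setNames(
    lapply(by_S, function(d) {
      induction_dataset(d$time_min, d$nucleated, volume_mL, censor_time,
                        S = d$supersaturation[1L], vial_id = d$vial_id)
    }),
    names(by_S)
  )
}

#' Read a particle-count table
#'
#' Expected columns: `vial_id`, `time_min`, `count`; optional
#' `supersaturation`. Returns one [count_series()] per vial.
#'
#' @param path CSV path.
#' @param calibration_factor (particles/mL) per (count/image).
#' @return Named list of `count_series` objects keyed by vial id.
#' @export
read_counts_csv <- function(path, calibration_factor = 100) {
  df <- utils::read.csv(path)
  require_columns(df, c("vial_id", "time_min", "count"), path)
  fails <- character(0)
  neg <- which(df$count < 0)
  if (length(neg)) fails <- c(fails, sprintf("row %d: negative count", neg))
  for (v in unique(df$vial_id)) {
    tv <- df$time_min[df$vial_id == v]
    if (any(diff(tv) <= 0)) {
      fails <- c(fails, sprintf("vial %s: time_min not strictly increasing", v))
    }
  }
  validate_or_stop(fails)
  by_v <- split(df, df$vial_id)
  stats::setNames(
    lapply(by_v, function(d) {
      count_series(d$time_min, d$count, calibration_factor,
                   S = if ("supersaturation" %in% names(d))
                     d$supersaturation[1L] else NA_real_,
                   vial_id = d$vial_id[1L])
    }),
    names(by_v)
  )
}

#' Read a long-format PSD table
#'
#' Expected columns: `vial_id`, `time_min`, `bin_index` (0-98), `count`; the
#' 3-300 um / 99-bin convention is implied. Every frame must carry all 99
#' bins. Returns one [psd_series()] per vial.
#'
#' @param path CSV path.
#' @return Named list of `psd_series` objects keyed by vial id.
#' @export
read_psd_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("vial_id", "time_min", "bin_index", "count"), path)
  fails <- character(0)
  if (any(df$bin_index < 0 | df$bin_index > 98)) {
    fails <- c(fails, "bin_index outside 0-98")
  }
  neg <- which(df$count < 0)
  if (length(neg)) fails <- c(fails, sprintf("row %d: negative count", neg))
  validate_or_stop(fails)
  by_v <- split(df, df$vial_id)
  out <- lapply(by_v, function(d) {
    times <- sort(unique(d$time_min))
    counts <- matrix(0L, nrow = length(times), ncol = 99L)
    for (i in seq_along(times)) {
      fr <- d[d$time_min == times[i], ]
      if (nrow(fr) != 99L) {
        stop_crystkin(sprintf(
          "vial %s, time %g: frame has %d bins, expected 99",
          fr$vial_id[1L], times[i], nrow(fr)), "crystkin_validation_error")
      }
      counts[i, fr$bin_index + 1L] <- fr$count
    }
    psd_series(times, counts)
  })
  stats::setNames(out, names(by_v))
}

#' Read a clear-point table
#'
#' Expected columns: `concentration_mg_per_g`, `heating_rate_C_per_min`,
#' `clear_point_C`, `replicate`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_clear_points_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("concentration_mg_per_g", "heating_rate_C_per_min",
                        "clear_point_C", "replicate"), path)
  bad <- which(df$heating_rate_C_per_min <= 0)
  validate_or_stop(if (length(bad))
    sprintf("row %d: non-positive heating rate", bad) else character(0))
  df
}

#' Read a solubility table
#'
#' Expected columns: `temperature_C`, `solubility_mg_per_g`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_solubility_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("temperature_C", "solubility_mg_per_g"), path)
  bad <- which(df$solubility_mg_per_g <= 0)
  validate_or_stop(if (length(bad))
    sprintf("row %d: non-positive solubility", bad) else character(0))
  df
}

#' Run the full kinetic-assessment pipeline
#'
#' Executes the workflow stages in campaign order -- solubility, unseeded
#' induction fits, seeded secondary-nucleation and growth rates, power laws,
#' single-nucleus mechanism syntheses, and (optionally) MSMPR guidance --
#' on whatever inputs are present, skipping dependent stages with an
#' explanation when an upstream stage fails or its inputs are missing. The
#' result is deterministic for fixed inputs.
#'
#' @param inputs Either a `workflow_suite` from [simulate_workflow_suite()],
#'   or a list with any of: `induction` (list of [induction_dataset()]),
#'   `counts` (list, or list of lists, of [count_series()]), `psd` (list of
#'   [psd_series()]; each needs an `S` field to join on supersaturation),
#'   `solubility` (data frame with `temperature_C`, `solubility_mg_per_g`).
#' @param msmpr_design Optional [msmpr_required_rates()] design point for the
#'   guidance stage.
#' @param min_nucleated Passed to [fit_induction_model()].
#' @return A list of class `crystkin_report` with one element per stage, each
#'   carrying results with explicit units, plus `errors` naming skipped or
#'   failed stages.
#' @export
run_pipeline <- function(inputs, msmpr_design = NULL, min_nucleated = 5L) {
  if (inherits(inputs, "workflow_suite")) {
    inputs <- list(induction = inputs$induction,
                   counts = inputs$counts, psd = inputs$psd)
  }
  if (!is.list(inputs) || length(inputs) == 0L ||
      !any(c("induction", "counts", "psd", "solubility") %in% names(inputs))) {
    stop_crystkin("no input datasets supplied", "crystkin_invalid_argument")
  }
  report <- list()
  errors <- character(0)

  if (!is.null(inputs$solubility)) {
    report$solubility <- tryCatch({
      m <- fit_vant_hoff(inputs$solubility$temperature_C,
                         inputs$solubility$solubility_mg_per_g)
      list(vant_hoff_intercept = m$intercept,
           vant_hoff_slope_K = m$slope_K, units = "ln(mg/g) vs 1/K")
    }, error = function(e) {
      errors <<- c(errors, paste("solubility:", conditionMessage(e)))
      NULL
    })
  }

  induction_fits <- list()
  if (!is.null(inputs$induction)) {
    for (ds in inputs$induction) {
      f <- tryCatch(fit_induction_model(ds, min_nucleated),
                    error = function(e) {
                      errors <<- c(errors, sprintf(
                        "induction (S = %g): %s", ds$S, conditionMessage(e)))
                      NULL
                    })
      if (!is.null(f)) induction_fits <- c(induction_fits, list(f))
    }
    report$primary_nucleation <- list(
      units = list(J = "nuclei/(mL min)", t_g = "min", MIT = "min"),
      fits = lapply(induction_fits, function(f) {
        list(S = f$S, J = f$J, J_se = f$J_se, t_g = f$t_g, t_g_se = f$t_g_se,
             M = f$M, n_nucleated = f$n_nucleated,
             MIT = min(f$cdf$time_min))
      })
    )
  }

  secondary_rates <- list()
  delays <- data.frame(S = numeric(0), delay = numeric(0))
  if (!is.null(inputs$counts)) {
    flat <- if (all(vapply(inputs$counts, inherits, logical(1),
                           "count_series"))) {
      inputs$counts
    } else {
      unlist(inputs$counts, recursive = FALSE)
    }
    for (cs in flat) {
      est <- tryCatch(estimate_secondary_rate(cs), error = function(e) {
        errors <<- c(errors, sprintf("secondary (S = %g): %s", cs$S,
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(est)) secondary_rates <- c(secondary_rates, list(est))
      d <- detect_delay_time(cs)
      if (!is.na(d)) {
        delays <- rbind(delays, data.frame(S = cs$S, delay = d))
      }
    }
    report$secondary_nucleation <- list(
      units = list(B = "particles/(mL min)", delay = "min"),
      rates = lapply(secondary_rates, function(r)
        list(S = r$S, B = r$value, se = r$se, r_squared = r$r_squared)),
      delays = delays
    )
  }

  growth_rates <- data.frame(S = numeric(0), G = numeric(0))
  if (!is.null(inputs$psd)) {
    for (ps in inputs$psd) {
      g <- tryCatch({
        estimate_growth_rate(d90_series(ps))
      }, error = function(e) {
        errors <<- c(errors, sprintf("growth (S = %g): %s", ps$S,
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(g)) {
        growth_rates <- rbind(growth_rates,
                              data.frame(S = ps$S, G = g$value))
      }
    }
    report$growth <- list(units = "um/min", rates = growth_rates)
  }

  # power laws ---------------------------------------------------------------
  growth_fit <- NULL
  if (nrow(growth_rates) >= 2L) {
    ok <- growth_rates$G > 0 & growth_rates$S > 1
    growth_fit <- tryCatch(
      fit_power_law(growth_rates$S[ok], growth_rates$G[ok], "growth"),
      error = function(e) {
        errors <<- c(errors, paste("growth power law:", conditionMessage(e)))
        NULL
      })
  }
  secondary_fit <- NULL
  if (length(secondary_rates) >= 2L) {
    S_B <- vapply(secondary_rates, function(r) r$S, numeric(1))
    B_v <- vapply(secondary_rates, function(r) r$value, numeric(1))
    ok <- B_v > 0 & S_B > 1
    if (sum(ok) >= 2L) {
      secondary_fit <- tryCatch(
        fit_power_law(S_B[ok], B_v[ok], "secondary_nucleation"),
        error = function(e) {
          errors <<- c(errors, paste("secondary power law:",
                                     conditionMessage(e)))
          NULL
        })
    }
  }
  report$power_laws <- list(
    growth = if (!is.null(growth_fit))
      list(k = growth_fit$k, n = growth_fit$n,
           r_squared = growth_fit$r_squared, units = "um/min at S-1=1"),
    secondary = if (!is.null(secondary_fit))
      list(k = secondary_fit$k, n = secondary_fit$n,
           r_squared = secondary_fit$r_squared,
           units = "particles/(mL min) at S-1=1")
  )

  # mechanism ----------------------------------------------------------------
  if (!is.null(growth_fit) && length(induction_fits) >= 2L) {
    S_fit <- vapply(induction_fits, function(f) f$S, numeric(1))
    inv_G <- 1 / evaluate_power_law(growth_fit, S_fit)
    t_g_hat <- vapply(induction_fits, function(f) f$t_g, numeric(1))
    mit <- vapply(induction_fits, function(f) min(f$cdf$time_min), numeric(1))
    mech <- list(units = list(L_sn = "um", t_min_delay = "min",
                              L_det = "um"))
    ok_tg <- t_g_hat > 0
    if (sum(ok_tg) >= 2L) {
      mech$L_sn_from_t_g <-
        offset_fit_through_origin(inv_G[ok_tg], t_g_hat[ok_tg])$L_sn_um
    }
    mech$L_sn_from_MIT <- offset_fit_through_origin(inv_G, mit)$L_sn_um
    if (nrow(delays) > 0L) {
      mean_delay <- tapply(delays$delay, delays$S, mean)
      S_d <- as.numeric(names(mean_delay))
      if (length(S_d) >= 3L) {
        df <- delay_fit_free_intercept(
          1 / evaluate_power_law(growth_fit, S_d), as.numeric(mean_delay))
        mech$t_min_delay_min <- df$t_min_delay_min
        mech$L_det_um <- df$L_det_um
      }
    }
    report$mechanism <- mech
  } else if (length(induction_fits) > 0L || length(secondary_rates) > 0L) {
    errors <- c(errors,
                "mechanism: skipped (needs a growth power law and >= 2 induction fits)")
  }

  # behavior assessment ------------------------------------------------------
  if (!is.null(growth_fit) &&
      (length(induction_fits) > 0L || length(secondary_rates) > 0L)) {
    report$behavior <- tryCatch(
      behavior_table(induction_fits, secondary_rates, growth_fit),
      error = function(e) {
        errors <<- c(errors, paste("behavior:", conditionMessage(e)))
        NULL
      })
  }

  # MSMPR guidance -----------------------------------------------------------
  if (!is.null(msmpr_design)) {
    if (!is.null(growth_fit) && !is.null(secondary_fit)) {
      op <- operating_point(msmpr_design, growth_fit, secondary_fit)
      report$msmpr <- list(
        units = list(G = "um/min", B = "particles/(mL min)"),
        G_required = msmpr_design$G_um_min,
        B_required = msmpr_design$B_per_mL_min,
        S_required = op$S_required,
        B_available = op$B_available_per_mL_min,
        feasible = op$feasible)
    } else {
      errors <- c(errors, "msmpr: skipped (needs growth and secondary power laws)")
    }
  }

  report$errors <- errors
  report$fits <- list(growth = growth_fit, secondary = secondary_fit,
                      induction = induction_fits)
  class(report) <- "crystkin_report"
  report
}

#' @export
print.crystkin_report <- function(x, ...) {
  cat("crystallization kinetics report\n")
  if (!is.null(x$solubility)) {
    cat(sprintf("  solubility: van't Hoff ln(C) = %.4g %+.4g / T(K)\n",
                x$solubility$vant_hoff_intercept,
                x$solubility$vant_hoff_slope_K))
  }
  if (!is.null(x$primary_nucleation)) {
    cat(sprintf("  primary nucleation: %d supersaturation(s) fitted\n",
                length(x$primary_nucleation$fits)))
    for (f in x$primary_nucleation$fits) {
      cat(sprintf("    S = %-5.3g  J = %.3g /(mL min)  t_g = %.3g min  (%d/%d nucleated)\n",
                  f$S, f$J, f$t_g, f$n_nucleated, f$M))
    }
  }
  if (!is.null(x$secondary_nucleation)) {
    cat(sprintf("  secondary nucleation: %d trace(s) fitted\n",
                length(x$secondary_nucleation$rates)))
  }
  if (!is.null(x$growth)) {
    cat(sprintf("  growth: %d supersaturation(s) with d90 slopes\n",
                nrow(x$growth$rates)))
  }
  if (!is.null(x$power_laws$growth)) {
    g <- x$power_laws$growth
    cat(sprintf("  growth power law:    G = %.4g (S-1)^%.3g um/min  (R^2 %.4f)\n",
                g$k, g$n, g$r_squared))
  }
  if (!is.null(x$power_laws$secondary)) {
    b <- x$power_laws$secondary
    cat(sprintf("  secondary power law: B = %.4g (S-1)^%.3g /(mL min)  (R^2 %.4f)\n",
                b$k, b$n, b$r_squared))
  }
  if (!is.null(x$mechanism)) {
    m <- x$mechanism
    if (!is.null(m$L_sn_from_t_g)) {
      cat(sprintf("  single-nucleus size L_sn: %.3g um (from t_g), %.3g um (from MIT)\n",
                  m$L_sn_from_t_g, m$L_sn_from_MIT))
    }
    if (!is.null(m$t_min_delay_min)) {
      cat(sprintf("  delay fit: minimum delay %.3g min, detectable size %.3g um\n",
                  m$t_min_delay_min, m$L_det_um))
    }
  }
  if (!is.null(x$msmpr)) {
    cat(sprintf("  MSMPR: S for required G = %.4g; B available %.4g vs required %.4g -> %s\n",
                x$msmpr$S_required, x$msmpr$B_available, x$msmpr$B_required,
                if (isTRUE(x$msmpr$feasible)) "feasible" else "infeasible"))
  }
  if (length(x$errors)) {
    cat("  stage notes:\n")
    for (e in x$errors) cat("    -", e, "\n")
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report A `crystkin_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "crystkin_report"))
  out <- report[setdiff(names(report), "fits")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
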