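#' A particle-count time series from in-situ imaging
#'
#' Counts of particles in focus per image, frame by frame, for one vial
#' following seed addition (or, for unseeded vials, re-zeroed at the
#' induction time). The calibration factor converts counts per image to a
#' number density in the vial.
#'
#' @param time_min Frame times, min, strictly increasing.
#' @param count Particles per image, >= 0.
#' @param calibration_factor (particles/mL) per (count/image), > 0.
#' @param S Supersaturation (optional metadata).
#' @param seed_size_um Nominal seed size, um (metadata; nominal 2500 +/- 1000).
#' @param vial_id Optional identifier.
#' @return An object of class `count_series`.
#' @export
count_series <- function(time_min, count, calibration_factor = 100,
                         S = NA_real_, seed_size_um = 2500, vial_id = NA) {
  if (length(time_min) != length(count)) {
    stop_crystkin("time_min and count lengths differ",
                  "crystkin_invalid_argument")
  }
  if (any(diff(time_min) <= 0)) {
    stop_crystkin("time_min must be strictly increasing",
                  "crystkin_invalid_argument")
  }
  if (any(count < 0)) {
    stop_crystkin("counts must be non-negative", "crystkin_invalid_argument")
  }
  check_positive(calibration_factor, "calibration_factor")
  structure(
    list(data = data.frame(time_min = time_min, count = count),
         calibration_factor = calibration_factor, S = S,
         seed_size_um = seed_size_um, vial_id = vial_id),
    class = "count_series"
  )
}

#' A time series of number-weighted size histograms
#'
#' @param time_min Frame times, min, strictly increasing.
#' @param counts Integer matrix, one row per frame, 99 columns (the linear
#'   detector bins over 3-300 um).
#' @param n_births Total particles born in the generating simulation
#'   (optional metadata used by conservation checks).
#' @param S Supersaturation (optional metadata).
#' @return An object of class `psd_series`.
#' @export
psd_series <- function(time_min, counts, n_births = NA_integer_,
                       S = NA_real_) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 99L) {
    stop_crystkin("PSD histograms must have exactly 99 bins",
                  "crystkin_invalid_argument")
  }
  if (nrow(counts) != length(time_min)) {
    stop_crystkin("one histogram row per frame time required",
                  "crystkin_invalid_argument")
  }
  if (any(counts < 0)) {
    stop_crystkin("histogram counts must be non-negative",
                  "crystkin_invalid_argument")
  }
  structure(
    list(time_min = time_min, counts = counts, bin_edges = psd_bin_edges(),
         n_births = n_births, S = S),
    class = "psd_series"
  )
}

#' Convert a count trace to a particle number density trace
#'
#' density = count x calibration factor, frame-wise.
#'
#' @param series A [count_series()].
#' @return Data frame with `time_min` and `density` (particles/mL).
#' @export
counts_to_density <- function(series) {
  stopifnot(inherits(series, "count_series"))
  data.frame(time_min = series$data$time_min,
             density = series$data$count * series$calibration_factor)
}

#' Delay time before detectable secondary nucleation
#'
#' First frame time at which the count reaches the detection threshold,
#' measured from seed addition at t = 0.
#'
#' @param series A [count_series()].
#' @param threshold Count threshold (>= 1; default 10, the background floor).
#' @return Delay in minutes, or `NA` if the threshold is never reached
#'   (not-detected, distinct from an error).
#' @export
detect_delay_time <- function(series, threshold = 10) {
  stopifnot(inherits(series, "count_series"))
  if (threshold < 1) {
    stop_crystkin("threshold must be >= 1", "crystkin_invalid_argument")
  }
  idx <- which(series$data$count >= threshold)
  if (length(idx) == 0L) return(NA_real_)
  series$data$time_min[idx[1L]]
}

#' Select the reliable imaging window of a count trace
#'
#' Imaging-based counting is reliable between a background floor and a
#' crowding ceiling. The window runs from the first frame with count >= low
#' through the last frame with count <= high before any frame exceeds high.
#'
#' @param series A [count_series()].
#' @param low,high Count bounds (defaults 10 and 160).
#' @return List `t_start`, `t_end`, `n_frames`.
#' @export
select_window <- function(series, low = 10, high = 160) {
  stopifnot(inherits(series, "count_series"))
  if (low >= high) {
    stop_crystkin("low must be < high", "crystkin_invalid_argument")
  }
  cnt <- series$data$count
  tm <- series$data$time_min
  i_lo <- which(cnt >= low)
  if (length(i_lo) == 0L) {
    stop_crystkin("count never reaches the lower bound",
                  "crystkin_insufficient_data")
  }
  i_lo <- i_lo[1L]
  over <- which(cnt > high)
  i_hi <- if (length(over) == 0L) length(cnt) else over[1L] - 1L
  if (i_hi - i_lo + 1L < 3L) {
    stop_crystkin("fewer than 3 frames in the count window",
                  "crystkin_insufficient_data")
  }
  list(t_start = tm[i_lo], t_end = tm[i_hi], n_frames = i_hi - i_lo + 1L)
}

ols_slope_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  # noise-free traces legitimately yield perfect fits
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[[2L]]),
       se = unname(sm$coefficients[2L, 2L]),
       intercept = unname(coef(fit)[[1L]]),
       r_squared = sm$r.squared)
}

#' Secondary nucleation rate from a density trace
#'
#' B is the OLS slope of the particle number density versus time within the
#' reliable imaging window.
#'
#' When no window is supplied, the 10-160 count window of the trace is used
#' and, when it holds at least five frames, its two boundary frames are
#' dropped from the fit: those frames enter the window conditional on their
#' own counting noise (the first frame crossed the floor, the last stayed
#' under the ceiling), which otherwise flattens the fitted slope by a few
#' percent. An explicitly supplied window is used verbatim.
#'
#' @param series A [count_series()].
#' @param window Optional list with `t_start`, `t_end` (as from
#'   [select_window()]); defaults to the 10-160 count window of the trace
#'   with boundary frames trimmed.
#' @return An object of class `rate_estimate` with `value` (particles/(mL
#'   min)), `se`, `window`, `n_frames`, `r_squared`, `kind = "B"` and a
#'   `quality_warning` flag when the fitted slope is negative.
#' @export
estimate_secondary_rate <- function(series, window = NULL) {
  stopifnot(inherits(series, "count_series"))
  if (is.null(window)) {
    w <- select_window(series)
    tm <- series$data$time_min
    i_lo <- which(tm == w$t_start)[1L]
    i_hi <- which(tm == w$t_end)[1L]
    if (i_hi - i_lo + 1L >= 5L) {
      i_lo <- i_lo + 1L
      i_hi <- i_hi - 1L
    }
    window <- list(t_start = tm[i_lo], t_end = tm[i_hi])
  }
  dens <- counts_to_density(series)
  keep <- dens$time_min >= window$t_start & dens$time_min <= window$t_end
  if (sum(keep) < 3L) {
    stop_crystkin("fewer than 3 frames in window",
                  "crystkin_insufficient_data")
  }
  f <- ols_slope_fit(dens$time_min[keep], dens$density[keep])
  # flag only meaningfully negative slopes, not numerical zero
  neg_tol <- 1e-8 * max(abs(dens$density[keep]), 1)
  structure(
    list(value = f$slope, se = f$se,
         window = c(t_start = window$t_start, t_end = window$t_end),
         n_frames = sum(keep), r_squared = f$r_squared, kind = "B",
         S = series$S, quality_warning = f$slope < -neg_tol),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  units <- if (x$kind == "B") "particles/(mL min)" else "um/min"
  cat(sprintf("%s = %.4g +/- %.2g %s  (window %.4g-%.4g min, %d frames, R^2 = %.3f)\n",
              x$kind, x$value, x$se, units,
              x$window[["t_start"]], x$window[["t_end"]],
              x$n_frames, x$r_squared))
  if (isTRUE(x$quality_warning)) cat("  warning: negative fitted slope\n")
  invisible(x)
}

#' Volume-weighted d90 trajectory of a PSD series
#'
#' Per frame, each bin is weighted by count x (bin midpoint)^3 (the shape
#' factor cancels in the volume fraction), and d90 -- the size below which
#' 90 percent of particle volume lies -- is found by linear interpolation of
#' the cumulative volume fraction within the containing bin. Frames with
#' fewer than `min_count` particles are skipped (background floor).
#'
#' @param psd A [psd_series()].
#' @param min_count Minimum frame total to yield a d90 value (default 10).
#' @param quantile Volume quantile (default 0.90; 0.50 gives d50).
#' @return Data frame with `time_min` and `d90` (um), skipped frames omitted.
#' @export
d90_series <- function(psd, min_count = 10, quantile = 0.90) {
  stopifnot(inherits(psd, "psd_series"))
  stopifnot(quantile > 0, quantile < 1)
  edges <- psd$bin_edges
  mids <- (edges[-1L] + edges[-100L]) / 2
  totals <- rowSums(psd$counts)
  keep <- which(totals >= min_count)
  d <- vapply(keep, function(i) {
    vol <- psd$counts[i, ] * mids^3
    cum <- cumsum(vol) / sum(vol)
    j <- which(cum >= quantile)[1L]
    below <- if (j == 1L) 0 else cum[j - 1L]
    frac <- (quantile - below) / (cum[j] - below)
    edges[j] + frac * (edges[j + 1L] - edges[j])
  }, numeric(1))
  data.frame(time_min = psd$time_min[keep], d90 = d)
}

#' Crystal growth rate from a d90 trajectory
#'
#' G is the OLS slope of the volume-weighted d90 versus time, using frames
#' within the reliable imaging window (when a window is supplied) since d90
#' tracks the largest particles and is insensitive to ongoing nucleation.
#'
#' @param d90 Data frame from [d90_series()].
#' @param window Optional list with `t_start`, `t_end` restricting the frames
#'   used.
#' @return A `rate_estimate` with `value` in um/min and `kind = "G"`.
#' @export
estimate_growth_rate <- function(d90, window = NULL) {
  stopifnot(is.data.frame(d90), all(c("time_min", "d90") %in% names(d90)))
  if (!is.null(window)) {
    d90 <- d90[d90$time_min >= window$t_start & d90$time_min <= window$t_end, ]
  }
  if (nrow(d90) < 3L) {
    stop_crystkin("fewer than 3 d90 points available",
                  "crystkin_insufficient_data")
  }
  f <- ols_slope_fit(d90$time_min, d90$d90)
  structure(
    list(value = f$slope, se = f$se,
         window = c(t_start = min(d90$time_min), t_end = max(d90$time_min)),
         n_frames = nrow(d90), r_squared = f$r_squared, kind = "G",
         S = NA_real_, quality_warning = f$slope < 0),
    class = "rate_estimate"
  )
}
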