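make_counts <- function(time, count, cal = 100) {
  count_series(time, count, calibration_factor = cal)
}

test_that("count-to-density conversion is the calibration product", {
  cs <- make_counts(1:5, c(0, 10, 50, 100, 200), cal = 100)
  dens <- counts_to_density(cs)
  expect_equal(dens$density, c(0, 1000, 5000, 10000, 20000))
  expect_error(count_series(1:3, c(0, 1, 2), calibration_factor = 0),
               class = "crystkin_invalid_argument")
  # shared-config round trip with the simulator
  cfg <- sim_config(B_true = 3000, delay_true = 5, calibration_factor = 100,
                    seed = 2)
  cs2 <- simulate_seeded_counts(cfg, 30, stochastic = FALSE)
  dens2 <- counts_to_density(cs2)
  after <- dens2$time_min > 5
  expect_equal(dens2$density[after], 3000 * (dens2$time_min[after] - 5),
               tolerance = 1e-10)
})

test_that("delay detection reports the first threshold crossing", {
  cs <- make_counts(0:10, c(0, 0, 0, 5, 12, 30, 60, 100, 140, 170, 200))
  expect_equal(detect_delay_time(cs, threshold = 10), 4)
  expect_true(is.na(detect_delay_time(make_counts(0:5, rep(0, 6)))))
  expect_equal(detect_delay_time(make_counts(0:3, c(1, 2, 3, 4)),
                                 threshold = 1), 0)
  expect_error(detect_delay_time(cs, threshold = 0),
               class = "crystkin_invalid_argument")
})

test_that("the reliable window spans counts 10 to 160", {
  cs <- make_counts(0:20, seq(0, 200, by = 10))
  w <- select_window(cs)
  expect_equal(unname(cs$data$count[cs$data$time_min == w$t_start]), 10)
  expect_equal(unname(cs$data$count[cs$data$time_min == w$t_end]), 160)
  # trace that never saturates: window runs to the last frame
  cs2 <- make_counts(0:10, c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50))
  w2 <- select_window(cs2)
  expect_equal(w2$t_end, 10)
  # degenerate jump straight past the ceiling
  cs3 <- make_counts(0:2, c(0, 5, 300))
  expect_error(select_window(cs3), class = "crystkin_insufficient_data")
})

test_that("secondary rate is the OLS density slope in the window", {
  t <- 5:20
  cs <- make_counts(t, 50 * (t - 5), cal = 100)  # density 5000*(t-5)
  est <- estimate_secondary_rate(cs, window = list(t_start = 5, t_end = 8))
  expect_equal(est$value, 5000, tolerance = 1e-9)
  # constant density: B = 0
  csc <- make_counts(1:10, rep(50, 10))
  est0 <- estimate_secondary_rate(csc, window = list(t_start = 1, t_end = 10))
  expect_equal(est0$value, 0)
  expect_false(est0$quality_warning)
  # negative slope flags a quality warning, not an error
  csn <- make_counts(1:10, seq(100, 10, by = -10))
  estn <- estimate_secondary_rate(csn, window = list(t_start = 1, t_end = 10))
  expect_true(estn$quality_warning)
})

test_that("mean secondary-rate estimate over noisy replicates is unbiased", {
  B_hat <- vapply(1:200, function(i) {
    cfg <- sim_config(B_true = 2000, delay_true = 5, seed = 5000 + i)
    estimate_secondary_rate(simulate_seeded_counts(cfg, 40))$value
  }, numeric(1))
  expect_lt(abs(mean(B_hat) - 2000) / 2000, 0.05)
})

test_that("doubling the calibration factor doubles the estimated B", {
  cfg <- sim_config(B_true = 2000, delay_true = 5, calibration_factor = 100,
                    seed = 55)
  cs <- simulate_seeded_counts(cfg, 40)
  cs2 <- count_series(cs$data$time_min, cs$data$count,
                      calibration_factor = 200)
  b1 <- estimate_secondary_rate(cs, window = list(t_start = 6, t_end = 12))
  b2 <- estimate_secondary_rate(cs2, window = list(t_start = 6, t_end = 12))
  expect_equal(b2$value, 2 * b1$value, tolerance = 1e-12)
})

test_that("d90 lies in the containing bin and above d50", {
  edges <- psd_bin_edges()
  # all particles in the bin [60, 63]
  h <- matrix(0, 1, 99)
  h[1, which(edges[-100] >= 60 & edges[-1] <= 63)] <- 50
  d <- d90_series(psd_series(1, h))
  expect_gte(d$d90, 60); expect_lte(d$d90, 63)
  # two bins with equal volume: d90 is inside the upper bin
  h2 <- matrix(0, 1, 99)
  mids <- (edges[-1] + edges[-100]) / 2
  h2[1, 10] <- round(1e6 / mids[10]^3)
  h2[1, 40] <- round(1e6 / mids[40]^3)
  d2 <- d90_series(psd_series(1, h2))
  expect_gte(d2$d90, edges[40]); expect_lte(d2$d90, edges[41])
  # d90 >= d50 frame-wise and scaling invariance
  set.seed(8)
  h3 <- matrix(rpois(99 * 5, 3), 5, 99)
  ps3 <- psd_series(1:5, h3)
  d90v <- d90_series(ps3, min_count = 1)$d90
  d50v <- d90_series(ps3, min_count = 1, quantile = 0.5)$d90
  expect_true(all(d90v >= d50v))
  expect_equal(d90_series(psd_series(1:5, h3 * 7), min_count = 1)$d90, d90v)
})

test_that("d90 agrees with the brute-force particle oracle within a bin", {
  set.seed(42)
  for (i in 1:100) {
    sizes <- runif(sample(100:500, 1), 3, 300)
    h <- matrix(histogram_particles(sizes), 1, 99)
    d <- d90_series(psd_series(1, h))$d90
    expect_lt(abs(d - d90_bruteforce(sizes)), 3)
  }
})

test_that("growth rate is the OLS d90 slope and needs three points", {
  d <- data.frame(time_min = 0:10, d90 = 20 + 12 * (0:10))
  expect_equal(estimate_growth_rate(d)$value, 12, tolerance = 1e-10)
  dfz <- data.frame(time_min = 0:10, d90 = rep(40, 11))
  expect_equal(estimate_growth_rate(dfz)$value, 0)
  expect_error(estimate_growth_rate(d[1:2, ]),
               class = "crystkin_insufficient_data")
})

test_that("noise-free d90 increments track G within one bin width", {
  cfg <- sim_config(B_true = 500, G_true = 6, seed = 3)
  ps <- simulate_psd_series(cfg, 30, stochastic = FALSE)
  d <- d90_series(ps)
  inc <- diff(d$d90)
  dt <- diff(d$time_min)
  expect_true(all(abs(inc - 6 * dt) <= 3 + 1e-9))
  g <- estimate_growth_rate(d)
  expect_lt(abs(g$value - 6) / 6, 0.1)
})
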