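test_that("empirical CDF counts nucleated vials over the full ensemble", {
  # 20 vials, 3 nucleated within the 4 h hold: P(240) = 0.15
  ds <- induction_dataset(
    time_min = c(100, 150, 200, rep(240, 17)),
    nucleated = c(rep(TRUE, 3), rep(FALSE, 17)),
    volume_mL = 3, censor_time = 240)
  cdf <- empirical_cdf(ds)
  expect_equal(max(cdf$P), 0.15)
  expect_equal(cdf$P[cdf$time_min == 200], 0.15)
  # ties merged: times (10, 10, 30) of M = 4
  ds2 <- induction_dataset(c(10, 10, 30, 240), c(1, 1, 1, 0),
                           censor_time = 240)
  cdf2 <- empirical_cdf(ds2)
  expect_equal(cdf2$time_min, c(10, 30))
  expect_equal(cdf2$P, c(0.5, 0.75))
  # all censored: empty step list
  ds3 <- induction_dataset(rep(240, 5), rep(FALSE, 5))
  expect_equal(nrow(empirical_cdf(ds3)), 0)
})

test_that("empirical CDF is a step function bounded by the nucleated fraction", {
  cfg <- sim_config(J_true = 5e-3, seed = 23)
  for (i in 1:10) {
    cfg$seed <- 23 + i
    ds <- simulate_induction_times(cfg, 40)
    cdf <- empirical_cdf(ds)
    if (nrow(cdf) == 0) next
    expect_true(all(diff(cdf$P) > 0))
    expect_true(all(cdf$P >= 0 & cdf$P <= 1))
    expect_equal(max(cdf$P), sum(ds$data$nucleated) / 40)
  }
})

test_that("model CDF has the offset-exponential form", {
  expect_equal(induction_probability(1e-3, 3, 37, 37), 0)
  expect_equal(induction_probability(1e-3, 3, 37, 20), 0)
  expect_equal(induction_probability(1e-3, 3, 37, 1e9), 1, tolerance = 1e-12)
  # Table-scale parameters, hand arithmetic: 1 - exp(-0.39)
  expect_equal(induction_probability(1.3e-3, 3, 37, 137),
               1 - exp(-1.3e-3 * 3 * 100), tolerance = 1e-15)
  expect_equal(round(induction_probability(1.3e-3, 3, 37, 137), 4), 0.3229)
  expect_error(induction_probability(1e-3, 3, 37, -1),
               class = "crystkin_invalid_argument")
})

test_that("noise-free CDF inversion recovers (J, t_g) to high precision", {
  cfg <- sim_config(J_true = 2e-3, V = 3, t_g_true = 20, seed = 1)
  ds <- simulate_induction_times(cfg, 500, stochastic = FALSE)
  f <- fit_induction_model(ds)
  expect_equal(f$J, 2e-3, tolerance = 1e-6)
  expect_equal(f$t_g, 20, tolerance = 1e-6)
  expect_lt(f$residual_norm, 1e-8)
})

test_that("fit residual at the optimum beats the truth on noisy data", {
  cfg <- sim_config(J_true = 5e-3, V = 3, t_g_true = 15, seed = 41)
  ds <- simulate_induction_times(cfg, 100)
  f <- fit_induction_model(ds)
  ssr_truth <- sum((f$cdf$P -
                      induction_probability(5e-3, 3, 15, f$cdf$time_min))^2)
  expect_lte(f$residual_norm^2, ssr_truth + 1e-12)
})

test_that("large stochastic ensembles recover Table-scale truth closely", {
  cfg <- sim_config(J_true = 1.3e-3, V = 3, t_g_true = 37, seed = 11)
  ds <- simulate_induction_times(cfg, 2e4)
  f <- fit_induction_model(ds)
  expect_lt(abs(f$J - 1.3e-3) / 1.3e-3, 0.03)
  expect_lt(abs(f$t_g - 37) / 37, 0.03)
})

test_that("modest ensembles recover J*V within a factor of two most of the time", {
  ok <- vapply(1:100, function(i) {
    cfg <- sim_config(J_true = 2.0e-2, V = 3, t_g_true = 8.7,
                      seed = 7000 + i)
    ds <- simulate_induction_times(cfg, 25)
    f <- tryCatch(fit_induction_model(ds), error = function(e) NULL)
    if (is.null(f)) return(FALSE)
    ratio <- (f$J * f$V) / (2.0e-2 * 3)
    ratio > 0.5 && ratio < 2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("insufficient nucleation raises an informative error", {
  ds <- induction_dataset(c(100, rep(240, 19)), c(1, rep(0, 19)))
  expect_error(fit_induction_model(ds), class = "crystkin_insufficient_data")
})

test_that("minimum induction time bounds the growth offset", {
  ds <- induction_dataset(c(100, 150, 200), c(1, 1, 1), censor_time = 240)
  expect_equal(minimum_induction_time(ds), 100)
  ds1 <- induction_dataset(c(130, 240), c(1, 0), censor_time = 240)
  expect_equal(minimum_induction_time(ds1), 130)
  expect_error(minimum_induction_time(
    induction_dataset(rep(240, 4), rep(0, 4))),
    class = "crystkin_insufficient_data")
  # the offset is a hard lower bound on any observed induction time
  cfg <- sim_config(J_true = 5e-3, t_g_true = 37, seed = 19)
  ds2 <- simulate_induction_times(cfg, 200)
  expect_gte(minimum_induction_time(ds2), 37)
})

test_that("fitted offset is consistent with the minimum induction time", {
  for (i in 1:20) {
    cfg <- sim_config(J_true = 5e-3, V = 3, t_g_true = 15, seed = 300 + i)
    ds <- simulate_induction_times(cfg, 50)
    f <- tryCatch(fit_induction_model(ds), error = function(e) NULL)
    if (is.null(f)) next
    expect_gte(minimum_induction_time(ds), f$t_g - 2 * max(f$t_g_se, 1e-6))
  }
})

test_that("censored-exponential MLE cross-checks the CDF fit", {
  cfg <- sim_config(J_true = 5e-3, V = 3, t_g_true = 15, seed = 91)
  ds <- simulate_induction_times(cfg, 5000)
  f <- fit_induction_model(ds)
  m <- fit_induction_mle(ds)
  expect_lt(abs(log(m$J / f$J)), log(1.2))
})
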