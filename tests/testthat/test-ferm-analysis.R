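test_that("unit conversions reproduce the calibration constants", {
  expect_equal(od_to_cdw(1.0), 0.313)
  expect_equal(od_to_cdw(0), 0)
  expect_equal(od_to_cdw(2.0), 0.626)      # linearity
  expect_error(od_to_cdw(-1), ">= 0")
  expect_equal(ethanol_mass(0), 0)
  expect_equal(ethanol_mass(96), 75.7, tolerance = 1e-3)
  expect_equal(ethanol_mass(9.63), 7.6, tolerance = 1e-3)  # the batch charge
  expect_error(ethanol_mass(-5), ">= 0")
})

test_that("space-time and biomass-normalised yields are plain ratios", {
  expect_equal(space_time_yield(5.3, 23), 0.230, tolerance = 5e-3)
  expect_equal(space_time_yield(0, 23), 0)
  expect_equal(space_time_yield(1.02, 48), 0.02125)
  expect_error(space_time_yield(1, 0), "> 0")
  expect_equal(product_to_biomass(0.94, 1.63), 0.577, tolerance = 1e-3)
  expect_equal(product_to_biomass(0, 5), 0)
  expect_error(product_to_biomass(1, 0), "> 0")
})

test_that("Cmol yields follow the congener split arithmetic", {
  # evolved producer on ethanol and the wild-type-background control
  expect_equal(round(cmol_yield(0.94, 0.23, 7.6, "ethanol"), 2), 0.15)
  expect_equal(round(cmol_yield(0.64, 0.13, 7.6, "ethanol"), 2), 0.10)
  expect_equal(cmol_yield(0, 0.5, 7.6, "ethanol"), 0)
  # homogeneity of degree zero in joint scaling
  y1 <- cmol_yield(0.94, 0.23, 7.6, "ethanol")
  expect_equal(cmol_yield(9.4, 0.23, 76, "ethanol"), y1)
  expect_error(cmol_yield(1, 1.2, 7.6, "ethanol"), "haa_fraction")
  expect_error(cmol_yield(1, 0.2, 0, "ethanol"), "> 0")
})

test_that("acetate correction substitutes carbon-equivalent ethanol", {
  y <- acetate_corrected_yield(5.3, 83.3, 10)
  expect_equal(y, 0.070, tolerance = 1e-2)
  # zero acetate reduces to the plain yield
  expect_equal(acetate_corrected_yield(5.3, 83.3, 0), 5.3 / 83.3)
  # more residual acetate -> strictly higher corrected yield
  expect_gt(acetate_corrected_yield(5.3, 83.3, 20), y)
  expect_error(acetate_corrected_yield(1, 5, 100), "denominator")
})

test_that("growth rate recovers exact exponentials and rejects short windows", {
  t <- seq(0, 5, by = 0.25)
  expect_equal(as.numeric(growth_rate(t, 0.1 * exp(0.51 * t))), 0.51,
               tolerance = 1e-9)
  expect_equal(as.numeric(growth_rate(t, rep(2, length(t)))), 0,
               tolerance = 1e-12)
  expect_error(growth_rate(t, 0.1 * exp(0.3 * t), window = 2), "3 points")
  expect_error(growth_rate(t, 0.1 * exp(0.3 * t), window = 100), "longer")
})

test_that("growth rate is recovered within 5% from noisy synthetic curves", {
  err <- vapply(1:100, function(seed) {
    d <- gen_growth_curve(mu = 0.51, lag = 6, od0 = 0.05, od_max = 5,
                          horizon = 24,
                          cfg = generator_config(seed = seed,
                                                 noise_cv = 0.02))
    # restrict to the clean exponential window after the lag
    idx <- d$t >= 7 & d$t <= 12
    mu_hat <- as.numeric(growth_rate(d$t[idx], d$od[idx], window = 12))
    abs(mu_hat - 0.51) / 0.51
  }, numeric(1))
  expect_lt(stats::quantile(err, 0.95), 0.05)
})

test_that("the 4-parameter logistic fit is exact on noiseless data", {
  t <- seq(0, 24, by = 0.5)
  y <- 0 + (22 - 0) / (1 + exp(-0.4 * (t - 12)))
  fit <- fit_logistic4(t, y)
  expect_true(fit$converged)
  expect_false(fit$boundary)
  expect_equal(fit$y_min, 0, tolerance = 1e-6)
  expect_equal(fit$y_max, 22, tolerance = 1e-6)
  expect_equal(fit$k, 0.4, tolerance = 1e-6)
  expect_equal(fit$t_m, 12, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  # falling sigmoids (batch ethanol) work too
  fit2 <- fit_logistic4(t, 7.6 - 7.6 / (1 + exp(-0.8 * (t - 8))))
  expect_equal(fit2$y_max - fit2$y_min, 7.6, tolerance = 1e-5)
})

test_that("logistic parameters are recovered within 5% under 2% CV noise", {
  t <- seq(0, 24, length.out = 50)
  truth <- c(y_min = 0, y_max = 22, k = 0.4, t_m = 12)
  y0 <- truth[["y_min"]] + (truth[["y_max"]] - truth[["y_min"]]) /
    (1 + exp(-truth[["k"]] * (t - truth[["t_m"]])))
  rel <- t(vapply(1:100, function(seed) {
    set.seed(seed)
    y <- y0 * (1 + stats::rnorm(length(t), 0, 0.02))
    f <- fit_logistic4(t, y)
    c(k = abs(f$k - 0.4) / 0.4,
      y_max = abs(f$y_max - 22) / 22,
      t_m = abs(f$t_m - 12) / 12)
  }, numeric(3)))
  expect_lt(stats::quantile(rel[, "k"], 0.95), 0.05)
  expect_lt(stats::quantile(rel[, "y_max"], 0.95), 0.05)
  expect_lt(stats::quantile(rel[, "t_m"], 0.95), 0.05)
})

test_that("degenerate inputs to the logistic fit are flagged, not silently fit", {
  t <- seq(0, 10, by = 0.5)
  expect_error(fit_logistic4(t[1:4], t[1:4]), "at least 5")
  expect_error(fit_logistic4(t, rep(3, length(t))), "constant")
  lin <- fit_logistic4(t, 1 + 2 * t)       # strictly linear input
  expect_true(lin$boundary)
})

test_that("the assembled yield report reproduces the printed fed-batch numbers", {
  yr <- fermentation_yields(titer = 5.3, haa_fraction = 0.23, cdw = 22,
                            duration = 23, batch_ethanol_g = 7.6,
                            fed_ml = 90, prime_ml = 6,
                            residual_acetate_g = 10)
  expect_equal(yr$yield_g_per_g, 0.064, tolerance = 1e-2)
  expect_equal(yr$space_time_yield, 0.23, tolerance = 1e-2)
  expect_equal(yr$acetate_corrected_yield, 0.070, tolerance = 1.5e-2)
  expect_gt(yr$yield_g_per_g_excl_prime, yr$yield_g_per_g)
  # the report echoes its inputs and constants for auditability
  expect_equal(yr$inputs$fed_ml, 90)
  expect_equal(yr$constants$ethanol_density, 0.789)
})
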