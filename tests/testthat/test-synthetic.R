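test_that("generators are bit-identical under a fixed seed", {
  cfg <- generator_config(seed = 11)
  expect_identical(gen_growth_curve(0.51, cfg = cfg),
                   gen_growth_curve(0.51, cfg = cfg))
  g1 <- gen_qpcr(c(a = 0.5), cfg = cfg)
  g2 <- gen_qpcr(c(a = 0.5), cfg = cfg)
  expect_identical(g1$table$data, g2$table$data)
  # different seeds differ
  expect_false(identical(
    gen_growth_curve(0.51, cfg = generator_config(seed = 1))$od,
    gen_growth_curve(0.51, cfg = generator_config(seed = 2))$od))
})

test_that("zero noise reproduces the model curves exactly", {
  cfg0 <- generator_config(seed = 3, noise_cv = 0)
  d <- gen_growth_curve(0.51, lag = 6, cfg = cfg0)
  expect_equal(d$od, attr(d, "truth"), tolerance = 1e-12)
  # the lag phase is flat at od0, growth follows afterwards
  expect_true(all(abs(d$od[d$t <= 6] - d$od[1]) < 1e-12))
  expect_gt(d$od[which(d$t > 8)[1]], d$od[1])

  g <- gen_fermentation(cfg0, fedbatch_config(hours = 3))
  expect_equal(g$series$X, g$truth$series$X, tolerance = 1e-12)
  expect_equal(g$series$S, g$truth$series$S, tolerance = 1e-12)
})

test_that("duplicate reactors differ only by measurement noise", {
  simcfg <- fedbatch_config(hours = 3)
  a <- gen_fermentation(generator_config(seed = 1, noise_cv = 0.02), simcfg)
  b <- gen_fermentation(generator_config(seed = 2, noise_cv = 0.02), simcfg)
  expect_identical(a$truth$series$X, b$truth$series$X)  # same underlying run
  expect_false(identical(a$series$X, b$series$X))       # different noise
})

test_that("the yield pipeline on noiseless output reproduces simulator truth", {
  g <- gen_fermentation(generator_config(seed = 5, noise_cv = 0),
                        fedbatch_config(hours = 16))
  s <- utils::tail(g$series, 1)
  truth <- utils::tail(g$truth$series, 1)
  yr <- fermentation_yields(
    titer = s$P, haa_fraction = 0.23, cdw = s$X, duration = s$t,
    batch_ethanol_g = 7.6,
    fed_ml = g$truth$cumulative_feed_ml - 6, prime_ml = 6,
    residual_acetate_g = s$A * s$V, volume = s$V)
  yr_truth <- fermentation_yields(
    titer = truth$P, haa_fraction = 0.23, cdw = truth$X, duration = truth$t,
    batch_ethanol_g = 7.6,
    fed_ml = g$truth$cumulative_feed_ml - 6, prime_ml = 6,
    residual_acetate_g = truth$A * truth$V, volume = truth$V)
  expect_equal(yr$yield_g_per_g, yr_truth$yield_g_per_g, tolerance = 1e-6)
  expect_equal(yr$yield_cmol_per_cmol, yr_truth$yield_cmol_per_cmol,
               tolerance = 1e-6)
})

test_that("qPCR generation honours its own dCt arithmetic", {
  cfg0 <- generator_config(seed = 9, noise_cv = 0)
  g <- gen_qpcr(c(g1 = 4), efficiency = 2, sigma_ct = 0, cfg = cfg0)
  # E = 2, fold = 4 -> dCt exactly 2 cycles
  d <- g$table$data
  ct_ref <- mean(d$ct[d$gene == "rpoB"])
  ct_g1 <- mean(d$ct[d$gene == "g1"])
  expect_equal(ct_ref - ct_g1, 2, tolerance = 1e-12)
  # and the estimator returns the true fold exactly
  expect_equal(as.numeric(relative_expression(g$table, "g1", "strain1")),
               4, tolerance = 1e-12)
  expect_error(gen_qpcr(c(a = -1)), "> 0")
})
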