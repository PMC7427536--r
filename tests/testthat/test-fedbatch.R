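test_that("the feed decision matches the published trigger logic", {
  cp <- control_params()
  expect_equal(feed_controller(list(t = 10, DO = 45, in_lockout_until = 0),
                               cp), 3)
  expect_null(feed_controller(list(t = 10, DO = 35, in_lockout_until = 0),
                              cp))
  # 2 min after the previous trigger: still inside the 5-min pause
  expect_null(feed_controller(
    list(t = 10 + 2 / 60, DO = 45, in_lockout_until = 10 + 5 / 60), cp))
  # exactly at the lockout boundary the pulse fires again
  expect_equal(feed_controller(
    list(t = 10 + 5 / 60, DO = 45, in_lockout_until = 10 + 5 / 60), cp), 3)
})

test_that("configuration inconsistencies are rejected at load", {
  expect_error(control_params(do_feed_on = 30, do_feed_off = 40),
               "do_feed_off")
  expect_error(control_params(pulse_volume = 0), "pulse_volume")
  expect_error(fedbatch_config(hours = 0), "hours")
  expect_error(fedbatch_config(V0 = 2), "nominal")
  expect_error(kinetic_params(Y_xs = 1.5))
})

test_that("a sterile reactor changes nothing and sits at the DO ceiling", {
  cfg <- fedbatch_config(hours = 2, od0 = 0)
  sim <- simulate_fedbatch(cfg)
  s <- sim$series
  expect_true(all(s$X == 0))
  expect_true(all(abs(s$S - s$S[1]) < 1e-9))
  expect_true(all(s$A == 0))
  expect_true(all(s$P == 0))
  expect_equal(max(abs(s$DO - 100)), 0, tolerance = 1e-9)  # air saturation
})

test_that("control correctness: spacing, thresholds and feed bookkeeping", {
  sim <- simulate_fedbatch(fedbatch_config(hours = 16))
  pulses <- sim$events[sim$events$type == "pulse", ]
  expect_gt(nrow(pulses), 2)
  # no two feed events closer than the lockout (5 min)
  expect_true(all(diff(pulses$t) >= 5 / 60 - 1e-9))
  # every pulse is 3 mL and the cumulative feed is the exact bookkeeping sum
  expect_true(all(pulses$volume_ml == 3))
  expect_equal(sim$cumulative_feed_ml,
               3 * nrow(pulses) +
                 sum(sim$events$volume_ml[sim$events$type == "prime"]))
  # carbon closes over the whole run
  expect_lt(sim$carbon$relative_error, 1e-6)
  # rpm never decreases (increase-only cascade)
  expect_true(all(diff(sim$series$rpm) >= 0))
  # liquid volume stays within the nominal reactor volume
  expect_true(all(sim$series$V <= sim$config$V_nominal + 1e-9))
})

test_that("batch-only mode: ethanol depletion followed by a sustained DO rise", {
  sim <- simulate_fedbatch(fedbatch_config(hours = 14, batch_only = TRUE))
  s <- sim$series
  expect_equal(nrow(sim$events), 0L)
  expect_equal(sim$cumulative_feed_ml, 0)
  i_dep <- which(s$S < 0.05)[1]
  expect_false(is.na(i_dep))           # ethanol runs out
  expect_true(all(s$DO[i_dep:nrow(s)] > 90))   # DO shoots to saturation
  expect_lt(s$DO[i_dep - 4], 40)       # and was low while growing
})

test_that("with recirculation off the foam bottle only fills", {
  sim <- simulate_fedbatch(fedbatch_config(hours = 12, recirc = FALSE))
  expect_true(all(diff(sim$series$V_foam) >= -1e-12))
  expect_gt(utils::tail(sim$series$V_foam, 1), 0)
})

test_that("single-step integration guards against bad steps", {
  y <- stats::setNames(numeric(11), rhamnoflux:::rf_state_names)
  y["MX"] <- 0.16; y["MS"] <- 7.6; y["V"] <- 1
  expect_error(fedbatch_step(y, dt = 0), "dt")
  y2 <- fedbatch_step(y, dt = 0.1, rpm = 500)
  expect_gt(y2[["MX"]], y[["MX"]])     # it grows
  expect_lt(y2[["MS"]], y[["MS"]])     # on ethanol
})

test_that("kLa is monotone nondecreasing in rpm", {
  kin <- kinetic_params()
  r <- seq(200, 1200, by = 100)
  expect_true(all(diff(kla(r, 0.1, kin)) >= 0))
})
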