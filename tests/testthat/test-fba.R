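test_that("a linear chain carries exactly its uptake bound", {
  sol <- fba(chain_model(uptake = 10))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_A_e"]), -10, tolerance = 1e-9)
})

test_that("fba objective equals brute-force enumeration on random toys", {
  set.seed(7)
  for (i in 1:40) {
    toy <- random_toy_lp(n_rxn = 6, n_met = 4)
    mets <- lapply(seq_len(4), function(k)
      metabolite(paste0("m", k, "_c"), formula = "C1"))
    rxns <- lapply(seq_len(6), function(j) {
      st <- toy$S[, j]
      names(st) <- paste0("m", 1:4, "_c")
      reaction(paste0("r", j), st[st != 0], toy$lb[j], toy$ub[j],
               is_pseudo = TRUE)
    })
    mod <- stoich_model(mets, rxns, objective = numeric(0))
    # maximise a single random reaction to exercise the fba() interface
    jmax <- which.max(abs(toy$obj))
    ref <- brute_force_lp(toy$S, toy$lb, toy$ub,
                          as.numeric(seq_len(6) == jmax))
    got <- fba(mod, objective = paste0("r", jmax), parsimonious = FALSE)
    expect_equal(got$status, ref$status)
    if (ref$status == "optimal") {
      expect_equal(got$objective_value, ref$value, tolerance = 1e-9)
    }
  }
})

test_that("inconsistent bounds yield infeasible status, never silent zeros", {
  m <- chain_model()
  m$reactions$AB$lower_bound <- 5
  m$reactions$AB$upper_bound <- 1    # bypass set_bounds validation
  sol <- fba(m)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
  expect_error(rhamnoflux:::rf_require_optimal(sol), "infeasible")
})

test_that("the parsimonious tie-break removes gratuitous cycles", {
  m <- chain_model()
  # add a futile A<->A' loop that any optimum may carry at arbitrary flux
  m <- add_reactions(m, list(
    reaction("loop1", c(A_c = -1, Ap_c = 1), -1000, 1000),
    reaction("loop2", c(Ap_c = -1, A_c = 1), -1000, 1000)),
    list(metabolite("Ap_c", formula = "C1")))
  sol <- fba(m)   # parsimonious by default
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["loop1"]), 0, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes["loop2"]), 0, tolerance = 1e-6)
  # steady state and bounds hold on the reported vector
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
})

test_that("yields respond correctly to uptake and product availability", {
  m <- core_extended()
  expect_equal(as.numeric(biomass_yield(m, "NAD", uptake = 0)), 0)
  # monotonicity in the uptake bound
  mu5 <- attr(biomass_yield(m, "NAD", uptake = 5), "growth_flux")
  mu10 <- attr(biomass_yield(m, "NAD", uptake = 10), "growth_flux")
  expect_gte(mu10, mu5 - 1e-9)
  # closing the product exchange forces a zero product optimum
  mc <- set_bounds(m, "EX_rhl_e", 0, 0)
  expect_equal(attr(product_yield(mc, "NAD"), "product_flux"), 0,
               tolerance = 1e-9)
  expect_error(product_yield(build_core_model(), "NAD"),
               "product exchange not found")
})

test_that("carbon closes at the optimum of the core model", {
  m <- set_uptake(apply_scenario(core_extended(), "NAD"), "etoh", 10)
  sol <- fba(m, objective = "BIOMASS")
  v <- sol$fluxes
  c_in <- -v[["EX_etoh_e"]] * 2
  c_out <- v[["EX_biomass"]] * 40.6 + v[["EX_co2_e"]] +
    v[["EX_ac_e"]] * 2 + v[["EX_rhl_e"]] * 26 + v[["EX_haa_e"]] * 20
  expect_equal(c_out / c_in, 1, tolerance = 1e-6)
})

test_that("scenario ordering: NAD yields are at least PQQ yields", {
  m <- core_extended()
  expect_gte(as.numeric(biomass_yield(m, "NAD")),
             as.numeric(biomass_yield(m, "PQQ")) - 1e-6)
  expect_gte(as.numeric(product_yield(m, "NAD")),
             as.numeric(product_yield(m, "PQQ")) - 1e-9)
})

test_that("flux_report extracts the requested fluxes and validates ids", {
  m <- set_uptake(apply_scenario(core_extended(), "PQQ"), "etoh", 10)
  sol <- fba(m, objective = "BIOMASS")
  fr <- flux_report(sol)
  expect_equal(fr$reaction, c("EX_o2_e", "ACONTa", "EX_co2_e", "EX_etoh_e"))
  expect_equal(fr$abs_flux[4], 10, tolerance = 1e-6)
  expect_true(all(fr$abs_flux >= 0))
  expect_error(flux_report(sol, "NOPE"), "unknown reaction")
  # all-zero vector reports zeros
  sol0 <- sol; sol0$fluxes[] <- 0
  expect_true(all(flux_report(sol0)$abs_flux == 0))
})

test_that("zero-growth carbon yields respect the conservation bound", {
  m <- core_extended()
  y_eth <- as.numeric(product_yield_zero_growth(m, "etoh"))
  y_glc <- as.numeric(product_yield_zero_growth(m, "glc__D"))
  expect_gt(y_eth, 0); expect_lt(y_eth, 1)
  expect_gt(y_glc, 0); expect_lt(y_glc, 1)
  expect_gt(y_eth, y_glc)   # ethanol beats glucose for this product
})
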