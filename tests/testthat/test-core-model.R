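test_that("every internal reaction of the core network is elementally balanced", {
  m <- core_extended()
  bal <- check_balances(m)
  expect_gt(nrow(bal), 40)
  expect_true(all(bal$balanced))
  # balance holds for all six tracked elements, not just carbon
  expect_true(all(abs(as.matrix(bal[, c("C", "H", "N", "O", "P", "S")])) < 1e-9))
})

test_that("no growth without a carbon source, growth on ethanol under both scenarios", {
  m <- core_extended()
  # with the maintenance demand relaxed, closed uptakes give exactly zero
  # growth; with NGAM > 0 the same model is infeasible (nothing can pay
  # the ATP bill), which fba() reports as a status, not as silent zeros
  m0 <- extend_with_rhamnolipid_pathway(build_core_model(ngam = 0))
  sol0 <- fba(m0, objective = "BIOMASS")
  expect_equal(sol0$objective_value, 0, tolerance = 1e-9)
  expect_equal(fba(m, objective = "BIOMASS")$status, "infeasible")
  for (sc in c("PQQ", "NAD")) {
    mu <- attr(biomass_yield(m, sc), "growth_flux")
    expect_gt(mu, 0)
  }
})

test_that("cofactor scenarios close exactly one ethanol-oxidation route", {
  m <- core_extended()
  mp <- apply_scenario(m, "PQQ")
  expect_equal(mp$reactions$ADH$upper_bound, 0)
  expect_equal(mp$reactions$PEDH$upper_bound, m$reactions$PEDH$upper_bound)
  mn <- apply_scenario(m, "NAD")
  expect_equal(mn$reactions$PEDH$upper_bound, 0)
  expect_gt(mn$reactions$ADH$upper_bound, 0)
  # idempotence
  expect_identical(apply_scenario(mp, "PQQ"), mp)
  # missing routes
  expect_error(apply_scenario(chain_model(), "PQQ"), "neither")
})

test_that("set_uptake follows the exchange sign convention and closes other carbon sources", {
  m <- set_uptake(core_extended(), "etoh", 10)
  expect_equal(m$reactions$EX_etoh_e$lower_bound, -10)
  expect_equal(m$reactions$EX_glc__D_e$lower_bound, 0)
  expect_equal(m$reactions$EX_o2_e$lower_bound, -RF_FLUX_MAX)  # O2 stays open
  # switching substrate closes ethanol again
  m2 <- set_uptake(m, "glc__D", 10)
  expect_equal(m2$reactions$EX_etoh_e$lower_bound, 0)
  expect_equal(m2$reactions$EX_glc__D_e$lower_bound, -10)
  expect_error(set_uptake(m, "notasubstrate", 10), "no exchange")
  expect_error(set_uptake(m, "etoh", -1), ">= 0")
})

test_that("rhamnolipid extension is reversible, conservative and carbon-correct", {
  m0 <- build_core_model()
  m1 <- extend_with_rhamnolipid_pathway(m0)
  added <- attr(m1, "rl_added")
  expect_true(all(c("RHLA", "RHLB") %in% added))
  # extension adds balanced reactions only
  expect_true(all(check_balances(m1)$balanced))
  # inverse: removing the added reactions restores the reaction set
  m_back <- remove_reactions(m1, added)
  expect_setequal(names(m_back$reactions), names(m0$reactions))
  # mono-rhamnolipid carries 26 carbons, HAA 20
  expect_equal(carbon_count(m1$metabolites$rhl_c), 26)
  expect_equal(carbon_count(m1$metabolites$haa_c), 20)
  # conservativity: added capability never decreases maximal growth
  mu0 <- attr(biomass_yield(m0, "NAD"), "growth_flux")
  mu1 <- attr(biomass_yield(m1, "NAD"), "growth_flux")
  expect_gte(mu1, mu0 - 1e-9)
  # positive product flux with ethanol uptake open
  py <- product_yield(m1, "NAD")
  expect_gt(attr(py, "product_flux"), 0)
  # unknown precursor ids produce a helpful error
  expect_error(
    extend_with_rhamnolipid_pathway(
      m0, precursor_ids = list(hdacp = "nosuch_c", acp = "ACP_c",
                               dtdprmn = "dtdprmn_c", dtdp = "dtdp_c",
                               h2o = "h2o_c")),
    "not found")
})
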