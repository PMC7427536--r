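test_that("a minimal hand-written SBML file round-trips identically", {
  path <- sbml_fixture_minimal(tempfile(fileext = ".xml"))
  m <- read_sbml(path)
  expect_equal(length(m$metabolites), 2L)
  expect_equal(length(m$reactions), 1L)
  expect_equal(m$reactions$r1$lower_bound, -7.5)
  expect_equal(m$reactions$r1$upper_bound, 42)
  expect_equal(m$reactions$r1$stoichiometry, c(m1 = -1, m2 = 1))
  expect_equal(carbon_count(m$metabolites$m1), 2)
})

test_that("malformed SBML produces errors, never partial models", {
  p1 <- tempfile(fileext = ".xml")
  writeLines("<sbml><model><listOfSpec", p1)      # truncated XML
  expect_error(read_sbml(p1))
  expect_error(read_sbml(tempfile()), "cannot read")
  # reaction without FBC bounds names the culprit
  p2 <- sbml_fixture_minimal(tempfile(fileext = ".xml"))
  txt <- readLines(p2)
  txt <- sub(' fbc:lowerFluxBound="lb1"', "", txt)
  writeLines(txt, p2)
  expect_error(read_sbml(p2), "r1.*lower")
  # dangling species reference
  p3 <- sbml_fixture_minimal(tempfile(fileext = ".xml"))
  txt <- readLines(p3)
  txt <- sub('speciesReference species="m2"',
             'speciesReference species="ghost"', txt)
  writeLines(txt, p3)
  expect_error(read_sbml(p3), "undeclared species")
})

test_that("write/read round-trip of the curated model preserves everything", {
  m <- core_extended()
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_setequal(names(m2$metabolites), names(m$metabolites))
  expect_setequal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    r <- m$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_equal(sort(names(r2$stoichiometry)), sort(names(r$stoichiometry)))
    expect_equal(r2$stoichiometry[names(r$stoichiometry)], r$stoichiometry,
                 info = id)
    expect_equal(r2$lower_bound, r$lower_bound, info = id)
    expect_equal(r2$upper_bound, r$upper_bound, info = id)
  }
  expect_equal(m2$objective, m$objective)
  expect_true(all(check_balances(m2)$balanced))
  # and the model still computes the same optimum
  s1 <- fba(set_uptake(apply_scenario(m, "NAD"), "etoh", 10), "BIOMASS")
  s2 <- fba(set_uptake(apply_scenario(m2, "NAD"), "etoh", 10), "BIOMASS")
  expect_equal(s2$objective_value, s1$objective_value, tolerance = 1e-9)
})

test_that("an independent SBML parser agrees on the model dimensions", {
  m <- core_extended()
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import libsbml; d = libsbml.readSBML('", path, "'); ",
    "m = d.getModel(); print(m.getNumSpecies(), m.getNumReactions())"))),
    stdout = TRUE, stderr = FALSE)
  counts <- as.integer(strsplit(trimws(out[length(out)]), " ")[[1]])
  expect_equal(counts[1], length(m$metabolites))
  expect_equal(counts[2], length(m$reactions))
})
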