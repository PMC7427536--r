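test_that("Ct tables are validated on assembly", {
  d <- data.frame(gene = c("rpoB", "pedH"), strain = "wt",
                  replicate = 1, ct = c(20, 22))
  expect_s3_class(qpcr_table(d), "qpcr_table")
  expect_error(qpcr_table(d[d$gene != "rpoB", ]), "reference gene")
  d2 <- d; d2$ct[1] <- -1
  expect_error(qpcr_table(d2), "Ct values")
  expect_error(qpcr_table(d[, 1:3]), "lacks column")
})

test_that("primer efficiency follows the two-fold dilution convention", {
  # perfect doubling: slope -1 per log2 dilution -> E = 2
  sc <- standard_curve(0:-6, 20 - (0:-6))   # Ct rises by 1 per dilution
  expect_equal(as.numeric(primer_efficiency(sc)), 2, tolerance = 1e-12)
  expect_equal(attr(primer_efficiency(sc), "slope"), -1)
  # log10 conversion: slope_log10 = slope * log2(10)
  expect_equal(attr(primer_efficiency(sc), "slope_log10"), -log2(10))
  # degenerate inputs
  expect_error(standard_curve(0:-1, c(20, 21)), "at least 4")
  expect_error(standard_curve(0:-6, 20 + (0:-6)), "inverted")
  # scale invariance in the concentration axis (shifting log2 dilutions)
  sc2 <- standard_curve((0:-6) - 5, 20 - (0:-6))
  expect_equal(sc2$efficiency, sc$efficiency)
})

test_that("estimated efficiencies fall in the observed 2-2.13 band for truth 2.10", {
  hits <- vapply(1:200, function(seed) {
    g <- gen_qpcr(c(gene1 = 1), efficiency = 2.10, sigma_ct = 0.1,
                  cfg = generator_config(seed = seed))
    e <- as.numeric(primer_efficiency(standard_curve(
      g$curves$gene1$log2_dilution, g$curves$gene1$ct)))
    e >= 2 && e <= 2.13
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("2^dCt expression behaves per definition and is plate-shift invariant", {
  d <- data.frame(gene = rep(c("rpoB", "g1", "g2"), each = 2),
                  strain = "wt", replicate = rep(1:2, 3),
                  ct = c(20, 20.2, 20, 20.2, 18, 18.2))
  tab <- qpcr_table(d)
  expect_equal(as.numeric(relative_expression(tab, "g1", "wt")), 1)
  expect_equal(as.numeric(relative_expression(tab, "g2", "wt")), 4,
               tolerance = 1e-9)
  expect_error(relative_expression(tab, "g3", "wt"), "not measured")
  # adding a constant to every Ct of the strain leaves folds unchanged
  d2 <- d; d2$ct <- d2$ct + 3.7
  expect_equal(as.numeric(relative_expression(qpcr_table(d2), "g2", "wt")),
               4, tolerance = 1e-9)
  # replicate spread is reported as min/max
  f <- relative_expression(tab, "g2", "wt")
  expect_lte(attr(f, "min"), as.numeric(f))
  expect_gte(attr(f, "max"), as.numeric(f))
  expect_equal(attr(f, "n_replicates"), 2L)
})

test_that("true folds are recovered within 10% at sigma_ct = 0.1", {
  rel <- vapply(1:100, function(seed) {
    g <- gen_qpcr(c(pedH = 0.25), efficiency = 2, sigma_ct = 0.1,
                  cfg = generator_config(seed = seed))
    f <- as.numeric(relative_expression(g$table, "pedH", "strain1"))
    abs(f - 0.25) / 0.25
  }, numeric(1))
  expect_lt(stats::quantile(rel, 0.95), 0.10)
})
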