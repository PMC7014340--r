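test_that("degenerate coefficient ranges give identical runs, ratios 100%", {
  ec <- as.data.frame(default_export_coefficients())
  ec$ec_min <- ec$ec_median
  ec$ec_max <- ec$ec_median
  net <- generate_network(6, 5, "lowland")
  s <- ec_sensitivity(net, ec = ec_table(ec))
  expect_equal(s$concentrations[, "min"], s$concentrations[, "median"])
  expect_equal(s$concentrations[, "max"], s$concentrations[, "median"])
  expect_true(all(abs(s$ratio_pct - 100) < 1e-9))
})

test_that("coefficient-range runs bracket the median run", {
  net <- generate_network(8, 9, "upland")
  s <- ec_sensitivity(net)
  expect_true(all(s$concentrations[, "min"] <= s$concentrations[, "median"]))
  expect_true(all(s$concentrations[, "median"] <= s$concentrations[, "max"]))
  # ratio layout: min and max settings as percentages of the default run,
  # checked against direct arithmetic on documented summary cells
  expect_equal(unname(100 * 1.5 / 2.1), 71.4, tolerance = 0.001)
  expect_equal(unname(100 * 2.6 / 2.1), 123.8, tolerance = 0.001)
  expect_equal(s$ratio_pct["lowest", "min"],
               100 * s$summary["lowest", "min"] / s$summary["lowest", "median"])
})

test_that("discharge multiplier 1 reproduces the baseline exactly", {
  net <- generate_network(6, 13, "mixed")
  s <- discharge_sensitivity(net, multipliers = c(0.9, 1.1))
  base <- phoscade:::routed_concentrations(route_network(net))
  expect_identical(unname(s$concentrations[, "x1.00"]), unname(base))
})

test_that("concentrations are non-increasing in the discharge multiplier", {
  net <- generate_network(10, 17, "lowland")
  s <- discharge_sensitivity(net, multipliers = c(0.90, 0.95, 1.05, 1.10))
  for (i in seq_len(nrow(s$concentrations))) {
    expect_true(all(diff(s$concentrations[i, ]) <= 1e-12))
  }
  expect_true(all(diff(s$summary["mean", ]) <= 1e-12))
})

test_that("summary statistics follow the fixed estimators", {
  got <- summary_stats(c(1, 2, 3))
  expect_equal(got[["mean"]], 2)
  expect_equal(got[["median"]], 2)
  expect_equal(got[["sd"]], 1)
  expect_equal(got[["se"]], 1 / sqrt(3))
  expect_equal(got[["minimum"]], 1)
  expect_equal(got[["maximum"]], 3)
  # percentiles: linear interpolation between order statistics
  expect_equal(summary_stats(0:10)[["p90"]], 9)
  expect_equal(summary_stats(c(1, 2, 3, 4))[["p90"]], 3.7)
})

test_that("one-at-a-time ranks parameters by effect on mean concentration", {
  expect_identical(nrow(one_at_a_time(generate_network(3, 1, "upland"),
                                      list())), 0L)
  net <- generate_network(6, 23, "upland")  # rural: tiny populations
  ranked <- one_at_a_time(net, list(
    ec_setting = c("min", "max"),
    urban_per_capita = c(0.45625, 1.825),   # halved and doubled defaults
    discharge_multiplier = c(1.0)))
  expect_identical(ranked$parameter[1], "ec_setting")
  ec_eff <- ranked$max_abs_rel_change[ranked$parameter == "ec_setting"]
  pc_eff <- ranked$max_abs_rel_change[ranked$parameter == "urban_per_capita"]
  expect_gt(ec_eff, pc_eff)
  # a zero-width grid has zero effect
  null_eff <- ranked$max_abs_rel_change[
    ranked$parameter == "discharge_multiplier"]
  expect_equal(null_eff, 0)
  expect_error(one_at_a_time(net, list(warp_factor = 1:2)),
               class = "domain_error")
})
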