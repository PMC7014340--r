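test_that("scenario application is pure and an empty change set is identity", {
  net <- generate_network(6, 21, "mixed")
  base1 <- run_pipeline(net)
  scen <- apply_scenario(net, list(sc_extra_source("C001", "fish_farm", 500),
                                   sc_climate_scale(precip_factor = 1.2)))
  run_pipeline(scen)
  base2 <- run_pipeline(net)
  expect_identical(base1, base2)
  expect_identical(run_pipeline(apply_scenario(net, list())), base1)
})

test_that("land transfer conserves area and rejects over-transfer", {
  net <- catchment_network(list(simple_catchment(
    parcels = data.frame(landcover = c("Arable", "Improved grassland"),
                         slope_degrees = c(2, 8), area_ha = c(100, 200)))))
  before <- sum(net$catchments$A$parcels$area_ha)
  moved <- apply_scenario(net, sc_land_transfer("A", "Improved grassland",
                                                "Arable", 150))
  p <- moved$catchments$A$parcels
  expect_equal(sum(p$area_ha), before)
  expect_equal(sum(p$area_ha[p$landcover == "Arable"]), 250)
  # slope band of the transferred area is preserved
  expect_setequal(p$slope_class[p$landcover == "Arable"], c("Low", "Medium"))
  expect_error(apply_scenario(net, sc_land_transfer("A", "Arable",
                                                    "Wetland", 500)),
               class = "domain_error")
  expect_error(apply_scenario(net, sc_extra_source("nope", "birds", 1)),
               class = "domain_error")
})

test_that("the all-arable what-if raises milton toward the measured value", {
  cs <- case_study("milton")
  base <- run_pipeline(cs$network)
  expect_equal(base$tp_lake_ugl, cs$expected$modelled_conc,
               tolerance = 1e-6)
  scen <- run_pipeline(apply_scenario(cs$network, cs$changes))
  expect_equal(scen$tp_lake_ugl, 37.4, tolerance = 0.002)
  # still under half of the measured 81.8 ug/l
  expect_lt(scen$tp_lake_ugl, cs$expected$measured_conc / 2)
  # area is conserved by the reassignment
  reassigned <- apply_scenario(cs$network, cs$changes)
  expect_equal(sum(reassigned$catchments$milton$parcels$area_ha),
               sum(cs$network$catchments$milton$parcels$area_ha))
})

test_that("the skene correction lowers the modelled concentration to ~60.4", {
  cs <- case_study("skene")
  base <- run_pipeline(cs$network)
  expect_equal(base$tp_lake_ugl, 135.4, tolerance = 1e-6)
  scen <- run_pipeline(apply_scenario(cs$network, cs$changes))
  expect_equal(scen$tp_lake_ugl, 60.4, tolerance = 0.002)
})

test_that("diff reports signed deltas and class transitions", {
  cs <- case_study("menteith")
  base <- run_pipeline(cs$network)
  expect_identical(nrow(diff_report(base, base)$transitions), 0L)
  expect_equal(diff_report(base, base)$deltas$delta_conc_ugl, 0)
  scen <- run_pipeline(apply_scenario(cs$network, cs$changes))
  d <- diff_report(base, scen)
  expect_equal(d$deltas$delta_load_kg_yr, 227)
  expect_identical(d$transitions$class_from, "High")
  expect_identical(d$transitions$class_to, "Good")
  other <- base
  other$waterbody_id <- "someone_else"
  expect_error(diff_report(base, other), class = "domain_error")
})

test_that("forcing the shallow preset on leven lowers the prediction by 7.9", {
  cs <- case_study("leven")
  base <- run_pipeline(cs$network)
  expect_equal(base$tp_lake_ugl, 53.8, tolerance = 1e-6)
  shallow <- run_pipeline(cs$network,
                          model_config(oecd = oecd_parameters(
                            depth_threshold = 10)))
  d <- diff_report(base, shallow)
  expect_equal(d$deltas$delta_conc_ugl, 45.9 - 53.8, tolerance = 0.01)
})

test_that("per-capita overrides travel with the scenario network", {
  net <- catchment_network(list(simple_catchment(urban = 100, septic = 100)))
  scen <- apply_scenario(net, sc_per_capita(urban = 0.6, septic = 0.6))
  base <- route_network(net)
  mod <- route_network(scen)
  expect_equal(mod$A$apportionment$loads[["urban"]], 60)
  expect_equal(mod$A$apportionment$loads[["septic"]], 60)
  expect_equal(base$A$apportionment$loads[["urban"]], 91.25)
})
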