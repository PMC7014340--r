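test_that("slope classification follows the lower-inclusive bands", {
  expect_identical(classify_slope(c(0, 3.99, 4, 7, 12.99, 13, 45)),
                   c("Low", "Low", "Medium", "Medium", "Medium", "High",
                     "High"))
  expect_error(classify_slope(-0.1), class = "domain_error")
})

test_that("land load is area times coefficient, summed over parcels", {
  ec <- default_export_coefficients()
  expect_equal(land_load(data.frame(landcover = "Arable", slope_degrees = 2,
                                    area_ha = 100), ec), 74.0)
  two <- data.frame(landcover = c("Improved grassland",
                                  "Coniferous plantation"),
                    slope_degrees = c(7, 20), area_ha = c(10, 10))
  expect_equal(land_load(two, ec), 6.65)
  expect_identical(land_load(NULL, ec), 0)
  expect_error(land_load(data.frame(landcover = "Asteroid",
                                    slope_degrees = 1, area_ha = 1), ec),
               regexp = "Asteroid", class = "lookup_error")
})

test_that("land load is additive over partitions, monotone in setting, and linear in area", {
  ec <- default_export_coefficients()
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      parcels <- data.frame(
        landcover = sample(landCoverCategories(), n, replace = TRUE),
        slope_degrees = runif(n, 0, 30),
        area_ha = runif(n, 0, 200))
      total <- land_load(parcels, ec)
      cut <- sample(n - 1, 1)
      expect_equal(land_load(parcels[seq_len(cut), ], ec) +
                     land_load(parcels[-seq_len(cut), ], ec), total)
      doubled <- parcels
      doubled$area_ha <- doubled$area_ha * 2
      expect_equal(land_load(doubled, ec), 2 * total)
      expect_lte(land_load(parcels, ec, "min"), total)
      expect_lte(total, land_load(parcels, ec, "max"))
    }
  })
})

test_that("population loads apply the per-capita rates", {
  expect_equal(population_loads(1000, 0), c(urban = 912.5, septic = 0))
  expect_equal(population_loads(0, 0), c(urban = 0, septic = 0))
  expect_equal(population_loads(0, 40), c(urban = 0, septic = 10.0))
  expect_equal(population_loads(100, 10, per_capita_rates(0.5, 0.6)),
               c(urban = 50, septic = 6))
  expect_error(population_loads(-1, 0), class = "domain_error")
})

test_that("extra sources sum additively with a per-source breakdown", {
  menteith <- data.frame(
    source_type = c("fish_farm", "fish_cage", "birds", "deposition"),
    load_kg_yr = c(22, 95, 60, 50))
  got <- extra_source_load(menteith)
  expect_equal(got$total, 227)
  expect_equal(got$by_source[["birds"]], 60)
  expect_equal(extra_source_load(NULL)$total, 0)
  expect_equal(extra_source_load(data.frame(source_type = "birds",
                                            load_kg_yr = 450))$total, 450)
  expect_error(extra_source_load(data.frame(source_type = "birds",
                                            load_kg_yr = -1)),
               class = "domain_error")
})

test_that("local sources combine land, population and extras", {
  sc <- simple_catchment(parcels = data.frame(landcover = "Arable",
                                              slope_class = "Low",
                                              area_ha = 329 / 0.74),
                         septic = 40)
  app <- local_sources(sc)
  expect_equal(app$total, 329 + 10)
  expect_equal(app$loads[["land"]], 329)
  expect_equal(sum(app$shares), 100)

  zero <- simple_catchment(parcels = data.frame(landcover = character(),
                                                slope_class = character(),
                                                area_ha = numeric()))
  expect_equal(local_sources(zero)$total, 0)

  # the documented revised budget: a 399 kg/yr baseline plus 227 of extras
  men <- case_study("menteith")
  scen <- apply_scenario(men$network, men$changes)
  expect_equal(local_sources(scen$catchments$menteith)$total, 626)
})

test_that("a wwtw override replaces the per-capita urban term", {
  sc <- simple_catchment(urban = 1000,
                         extras = data.frame(source_type = "wwtw_override",
                                             load_kg_yr = 123))
  app <- local_sources(sc)
  expect_equal(app$loads[["urban"]], 123)
  no_override <- simple_catchment(urban = 1000)
  expect_equal(local_sources(no_override)$loads[["urban"]], 912.5)
  zeroed <- simple_catchment(urban = 1000,
                             extras = data.frame(source_type = "wwtw_override",
                                                 load_kg_yr = 0))
  expect_equal(local_sources(zeroed)$loads[["urban"]], 0)
})
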