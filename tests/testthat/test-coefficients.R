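test_that("packaged defaults reproduce the documented constants", {
  d <- load_defaults()
  expect_identical(d$rates$urban, 0.9125)
  expect_identical(d$rates$septic, 0.25)
  expect_identical(d$oecd$depth_threshold, 3.0)
  expect_identical(unname(d$oecd$shallow), c(1.02, 0.88))
  expect_identical(unname(d$oecd$combined), c(1.55, 0.82))
})

test_that("median export coefficients match the registry table exactly", {
  ec <- default_export_coefficients()
  medians <- list(
    Water = c(0.135, 0.135, 0.135),
    Wetland = c(0.085, 0.085, 0.085),
    `Blanket bog & peatland` = c(0.020, 0.030, 0.040),
    Arable = c(0.740, 1.140, 1.540),
    `Improved grassland` = c(0.320, 0.470, 0.620),
    Cliffs = c(0.045, 0.045, 0.045),
    `Montane vegetation` = c(0.025, 0.040, 0.060),
    `Low scrub` = c(0.140, 0.190, 0.240),
    `Broadleaved woodland` = c(0.150, 0.215, 0.275),
    `Coniferous plantation` = c(0.100, 0.145, 0.195),
    `Recently ploughed land` = c(0.560, 0.760, 0.960),
    `Woodland recently felled` = c(0.360, 0.560, 0.760),
    Ripping = c(0.300, 0.365, 0.425),
    `Factories & urban` = c(1.380, 2.105, 2.830))
  medians[[grass_cat]] <- c(0.060, 0.090, 0.115)
  medians[["Mixed woodland, Open canopy young plantation"]] <-
    c(0.125, 0.175, 0.235)
  medians[["Estuary, Salt marsh, Dune land, Maritime grasslands & heaths"]] <-
    c(0, 0, 0)
  medians[["Airfields, Recreational land, Quarries, Other land, Road & rail"]] <-
    c(0, 0, 0)
  expect_setequal(names(medians), landCoverCategories())
  for (cat in names(medians)) {
    vals <- vapply(slopeClasses(), function(s) {
      phoscade:::ec_lookup(ec, cat, s, "median")
    }, 0)
    expect_identical(vals, stats::setNames(medians[[cat]], slopeClasses()),
                     label = cat)
  }
})

test_that("range anchors and ordering hold across the table", {
  ec <- default_export_coefficients()
  expect_true(all(ec$ec_min <= ec$ec_median))
  expect_true(all(ec$ec_median <= ec$ec_max))
  expect_true(all(ec$ec_min >= 0))
  wet <- ec[ec$category == "Wetland" & ec$slope_class == "Low", ]
  expect_equal(wet$ec_max / wet$ec_min, 7.5)
  gr <- ec[ec$category == grass_cat & ec$slope_class == "High", ]
  expect_equal(gr$ec_max / gr$ec_min, 1.875)
  expect_identical(c(gr$ec_min, gr$ec_max), c(0.08, 0.15))
})

test_that("single-coefficient categories are slope invariant", {
  ec <- default_export_coefficients()
  for (cat in c("Water", "Wetland", "Cliffs")) {
    vals <- vapply(slopeClasses(), function(s) {
      phoscade:::ec_lookup(ec, cat, s, "median")
    }, 0)
    expect_length(unique(vals), 1)
  }
})

test_that("coefficient table round-trips through file exactly", {
  ec <- default_export_coefficients()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_export_coefficients(ec, tmp)
  back <- read_export_coefficients(tmp)
  expect_identical(as.data.frame(ec), as.data.frame(back))
})

test_that("malformed tables and unknown categories are rejected", {
  ec <- as.data.frame(default_export_coefficients())
  bad <- ec
  bad$category[1] <- "Lunar regolith"
  expect_error(ec_table(bad), class = "config_error")
  bad <- ec
  bad$ec_min[5] <- bad$ec_max[5] + 1
  expect_error(ec_table(bad), class = "config_error")
  expect_error(ec_table(ec[-1, ]), class = "config_error")
  expect_error(per_capita_rates(urban = -1), class = "domain_error")
  expect_error(oecd_parameters(shallow_b = 1.2), class = "domain_error")
  expect_error(oecd_parameters(depth_threshold = 0), class = "domain_error")
})
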