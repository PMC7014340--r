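bp <- c(hg = 10, gm = 20, mp = 40, pb = 80)

test_that("WFD status is boundary-inclusive upward and monotone", {
  expect_identical(wfd_status(0, bp), "High")
  expect_identical(wfd_status(20, bp), "Good")
  expect_identical(wfd_status(20.0001, bp), "Moderate")
  expect_identical(wfd_status(1000, bp), "Bad")
  conc <- seq(0, 120, by = 0.5)
  ranks <- wfd_rank(wfd_status(conc, bp))
  expect_true(all(diff(ranks) >= 0))
})

test_that("the skene breakpoints classify its measured and modelled values", {
  cs <- case_study("skene")
  sk_bp <- cs$network$breakpoints
  expect_identical(wfd_status(96.3, sk_bp), "Poor")
  expect_identical(wfd_status(135.4, sk_bp), "Bad")
  expect_identical(wfd_status(60.4, sk_bp), "Poor")
})

test_that("trophic classes split at 10 and 20 ug/l, boundaries mesotrophic", {
  expect_identical(trophic_class(c(5.5, 10, 15, 20, 27.7)),
                   c("oligotrophic", "mesotrophic", "mesotrophic",
                     "mesotrophic", "eutrophic"))
})

test_that("traffic light flags proximity to the target boundary", {
  expect_identical(traffic_light(0, bp), "green")
  expect_identical(traffic_light(20, bp), "amber")       # at the boundary
  expect_identical(traffic_light(18.5, bp), "amber")     # within 10% below
  expect_identical(traffic_light(17.9, bp), "green")
  expect_identical(traffic_light(20.2, bp), "red")
  expect_identical(traffic_light(45, bp, target_boundary = "mp"), "red")
  expect_error(traffic_light(5, bp, amber_fraction = 0), class = "domain_error")
})

test_that("headroom is the load to the current class boundary", {
  lake <- water_body("wb", 2, 6)
  q <- 2e7
  # load placing the lake exactly at the high/good boundary -> zero headroom
  at_hg <- load_for_concentration(10, q, lake)
  h <- headroom_load(at_hg, q, lake, bp)
  expect_equal(h$headroom_kg_yr, 0, tolerance = 1e-9)
  expect_identical(h$class, "High")
  # headroom decreases strictly with load within a class
  loads <- seq(at_hg * 0.2, at_hg * 0.99, length.out = 10)
  hr <- vapply(loads, function(L) {
    headroom_load(L, q, lake, bp)$headroom_kg_yr
  }, 0)
  expect_true(all(diff(hr) < 0))
  expect_true(all(hr >= 0))
  # consuming more than the headroom flips the class
  h2 <- headroom_load(at_hg * 0.5, q, lake, bp)
  flipped <- lake_concentration(at_hg * 0.5 + 1.01 * h2$headroom_kg_yr, q,
                                lake)
  expect_identical(wfd_status(flipped$tp_lake, bp), "Good")
  # beyond the worst boundary there is no headroom left
  bad <- headroom_load(at_hg * 100, q, lake, bp)
  expect_identical(bad$class, "Bad")
  expect_true(bad$boundary_exceeded)
  expect_equal(bad$headroom_kg_yr, 0)
})

test_that("adding the historic extras moves the menteith status High to Good", {
  cs <- case_study("menteith")
  base <- run_pipeline(cs$network)
  expect_identical(base$wfd_class, "High")
  revised <- run_pipeline(apply_scenario(cs$network, cs$changes))
  expect_identical(revised$wfd_class, "Good")
})

test_that("comparison matrix counts and agreement percentages", {
  cls <- wfdClasses()
  ident <- comparison_matrix(cls, cls)
  expect_equal(ident$exact_pct, 100)
  expect_true(all(ident$counts[row(ident$counts) != col(ident$counts)] == 0))
  one <- comparison_matrix("Good", "High")
  expect_equal(one$counts["High", "Good"], 1)
  expect_equal(one$exact_pct, 0)
  expect_equal(one$within_pct[["k1"]], 100)
  expect_error(comparison_matrix(c("High", "Good"), "High"),
               class = "domain_error")
  expect_error(comparison_matrix("High", "Pristine"), class = "domain_error")
})

test_that("the packaged 323-site comparison fixture reproduces its summary", {
  path <- system.file("extdata", "class_comparison_counts.csv",
                      package = "phoscade")
  counts <- read.csv(path, stringsAsFactors = FALSE)
  modelled <- rep(counts$modelled, counts$count)
  measured <- rep(counts$measured, counts$count)
  cm <- comparison_matrix(modelled, measured)
  expect_equal(cm$n, 323)
  # oracle: straight arithmetic on the count table
  expect_equal(cm$exact_pct, 100 * 175 / 323, tolerance = 1e-12)
  expect_equal(cm$exact_pct, 54.2, tolerance = 0.001)
  expect_equal(cm$within_pct[["k1"]], 100 * (175 + 108) / 323,
               tolerance = 1e-12)
  expect_equal(cm$within_pct[["k1"]], 87.6, tolerance = 0.001)
  expect_equal(sum(cm$counts), 323)
  expect_equal(cm$counts["High", "High"], 146)
})
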