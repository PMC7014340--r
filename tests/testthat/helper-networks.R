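# Fixture builders and independent oracles shared across test files.

grass_cat <- "Coarse grassland, Smooth grassland, Heather all types, Bracken"

simple_catchment <- function(id = "A", downstream = NA, area = 1000,
                             parcels = NULL, urban = 0, septic = 0,
                             extras = NULL, precip = 1450, pet = 450,
                             lake = NULL) {
  if (is.null(parcels)) {
    parcels <- data.frame(landcover = "Improved grassland",
                          slope_degrees = 2, area_ha = 500)
  }
  sub_catchment(catchment_id = id, downstream_id = downstream,
                land_area_ha = area, parcels = parcels,
                urban_population = urban,
                riparian_septic_population = septic,
                extra_sources = extras, precip_mm = precip, pet_mm = pet,
                lake = lake)
}

chain_network <- function(n = 3, lake_at = integer(), depth = 5) {
  ids <- LETTERS[seq_len(n)]
  catchments <- lapply(seq_len(n), function(i) {
    lk <- if (i %in% lake_at) {
      water_body(paste0("WB", ids[i]), 1, depth)
    }
    simple_catchment(ids[i],
                     downstream = if (i < n) ids[i + 1] else NA,
                     lake = lk)
  })
  catchment_network(catchments)
}

# Brute-force load accumulation for lake-free networks: a node's exported
# load is the sum of local totals over every node whose downstream chain
# passes through it (itself included).  Independent of route_network's
# single-pass accumulation.
brute_force_exports <- function(network, ec = default_export_coefficients(),
                                rates = per_capita_rates(),
                                setting = "median") {
  cs <- network$catchments
  local <- vapply(cs, function(s) local_sources(s, ec, rates, setting)$total,
                  0)
  down <- vapply(cs, `[[`, "", "downstream_id")
  exported <- stats::setNames(numeric(length(cs)), names(cs))
  for (u in names(cs)) {
    v <- u
    repeat {
      exported[[v]] <- exported[[v]] + local[[u]]
      v <- down[[v]]
      if (is.na(v)) break
    }
  }
  exported
}

# Same path enumeration for discharge accumulation (lakes pass water).
brute_force_discharge <- function(network) {
  cs <- network$catchments
  local_q <- vapply(cs, function(s) {
    annual_discharge(annual_runoff(s$precip_mm, s$pet_mm) * s$runoff_coeff,
                     s$land_area_ha)
  }, 0)
  down <- vapply(cs, `[[`, "", "downstream_id")
  q <- stats::setNames(numeric(length(cs)), names(cs))
  for (u in names(cs)) {
    v <- u
    repeat {
      q[[v]] <- q[[v]] + local_q[[u]]
      v <- down[[v]]
      if (is.na(v)) break
    }
  }
  q
}

# A small random lake-free network (distinct generator from the package's
# profile-based one, so routing tests do not lean on generate_network).
random_bare_network <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- paste0("N", seq_len(n))
    catchments <- lapply(seq_len(n), function(i) {
      ds <- if (i == 1) NA else ids[sample.int(i - 1, 1)]
      simple_catchment(ids[i], downstream = ds,
                       area = runif(1, 200, 2000),
                       parcels = data.frame(
                         landcover = sample(c("Arable", grass_cat,
                                              "Improved grassland"), 1),
                         slope_degrees = runif(1, 0, 20),
                         area_ha = runif(1, 50, 150)),
                       urban = sample(0:500, 1), septic = sample(0:50, 1),
                       precip = runif(1, 700, 2200), pet = runif(1, 350, 550))
    })
    catchment_network(catchments)
  })
}
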