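#' Standing-water body morphometry
#'
#' @param waterbody_id Identifier string.
#' @param surface_area_km2 Lake surface area in km^2 (> 0).
#' @param mean_depth_m Mean depth in m (> 0).
#' @param volume_m3 Lake volume in m^3; defaults to
#'   `surface_area_km2 * 1e6 * mean_depth_m`.
#' @return A list of class `"water_body"`.
#' @export
water_body <- function(waterbody_id, surface_area_km2, mean_depth_m,
                       volume_m3 = NULL) {
  if (!is.character(waterbody_id) || length(waterbody_id) != 1 ||
      !nzchar(waterbody_id)) {
    phos_error("waterbody_id must be a non-empty string", "domain_error")
  }
  if (!is.numeric(surface_area_km2) || surface_area_km2 <= 0) {
    phos_error("surface_area_km2 must be positive", "domain_error")
  }
  if (!is.numeric(mean_depth_m) || mean_depth_m <= 0) {
    phos_error("mean_depth_m must be positive", "domain_error")
  }
  if (is.null(volume_m3) || is.na(volume_m3)) {
    volume_m3 <- surface_area_km2 * 1e6 * mean_depth_m
  }
  if (volume_m3 <= 0) phos_error("volume_m3 must be positive", "domain_error")
  structure(list(waterbody_id = waterbody_id,
                 surface_area_km2 = as.numeric(surface_area_km2),
                 mean_depth_m = as.numeric(mean_depth_m),
                 volume_m3 = as.numeric(volume_m3)),
            class = "water_body")
}

# Normalise a parcel table: accepts slope_degrees and/or slope_class and
# returns columns landcover, slope_class, area_ha (slope_degrees kept if given).
normalize_parcels <- function(parcels) {
  if (is.null(parcels) || (is.data.frame(parcels) && nrow(parcels) == 0)) {
    return(data.frame(landcover = character(), slope_class = character(),
                      area_ha = numeric(), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(parcels)) {
    phos_error("parcels must be a data.frame", "domain_error")
  }
  if (!"landcover" %in% names(parcels) || !"area_ha" %in% names(parcels)) {
    phos_error("parcels need columns landcover and area_ha", "domain_error")
  }
  if (!"slope_class" %in% names(parcels)) {
    if (!"slope_degrees" %in% names(parcels)) {
      phos_error("parcels need slope_degrees or slope_class", "domain_error")
    }
    parcels$slope_class <- classify_slope(parcels$slope_degrees)
  }
  if (!all(parcels$slope_class %in% slopeClasses())) {
    phos_error("invalid slope_class in parcels", "domain_error")
  }
  bad <- setdiff(unique(parcels$landcover), landCoverCategories())
  if (length(bad)) {
    phos_error(sprintf("unknown land-cover category: %s",
                       paste(sQuote(bad), collapse = ", ")), "lookup_error")
  }
  if (any(is.na(parcels$area_ha)) || any(parcels$area_ha < 0)) {
    phos_error("parcel areas must be non-negative", "domain_error")
  }
  parcels
}

# Normalise an extra-source table: columns source_type, load_kg_yr.
normalize_extras <- function(extras) {
  if (is.null(extras) || (is.data.frame(extras) && nrow(extras) == 0)) {
    return(data.frame(source_type = character(), load_kg_yr = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!is.data.frame(extras) ||
      !all(c("source_type", "load_kg_yr") %in% names(extras))) {
    phos_error("extra_sources need columns source_type and load_kg_yr",
               "domain_error")
  }
  bad <- setdiff(unique(extras$source_type), extraSourceTypes())
  if (length(bad)) {
    phos_error(sprintf("unknown extra-source type: %s",
                       paste(sQuote(bad), collapse = ", ")), "domain_error")
  }
  if (any(is.na(extras$load_kg_yr)) || any(extras$load_kg_yr < 0)) {
    phos_error("extra-source loads must be non-negative", "domain_error")
  }
  extras
}

#' Construct a sub-catchment node
#'
#' A sub-catchment carries its local phosphorus sources (land-cover parcels,
#' urban population discharging through waste-water treatment, riparian
#' septic-tank population, additive extra sources), its annual climate
#' (precipitation and potential evapotranspiration, mm/yr), an optional
#' standing water at its outlet, and the identifier of the sub-catchment it
#' drains to.
#'
#' @param catchment_id Identifier string.
#' @param downstream_id Identifier of the receiving sub-catchment, or `NA`/""
#'   for an outlet.
#' @param land_area_ha Catchment land area, ha.
#' @param parcels data.frame with columns `landcover`, `slope_degrees` (or
#'   `slope_class`), `area_ha`.  Parcel areas must not exceed `land_area_ha`;
#'   unmapped remainder contributes no load.
#' @param urban_population,riparian_septic_population Person counts, >= 0.
#' @param extra_sources data.frame with columns `source_type` (one of
#'   fish_farm, fish_cage, birds, deposition, wwtw_override, other) and
#'   `load_kg_yr`.
#' @param precip_mm,pet_mm Annual precipitation and potential
#'   evapotranspiration, mm/yr.
#' @param runoff_coeff Optional multiplier on annual runoff (default 1), a
#'   hook for emulating soil-hydrology effects.
#' @param lake Optional [water_body()].
#' @return A list of class `"sub_catchment"`.
#' @export
sub_catchment <- function(catchment_id, downstream_id = NA, land_area_ha,
                          parcels = NULL, urban_population = 0,
                          riparian_septic_population = 0,
                          extra_sources = NULL, precip_mm, pet_mm,
                          runoff_coeff = 1, lake = NULL) {
  if (!is.character(catchment_id) || length(catchment_id) != 1 ||
      !nzchar(catchment_id)) {
    phos_error("catchment_id must be a non-empty string", "domain_error")
  }
  if (length(downstream_id) != 1) {
    phos_error("downstream_id must be a single value", "domain_error")
  }
  if (is.null(downstream_id) || is.na(downstream_id) ||
      identical(downstream_id, "")) {
    downstream_id <- NA_character_
  }
  if (!is.numeric(land_area_ha) || land_area_ha < 0) {
    phos_error("land_area_ha must be non-negative", "domain_error")
  }
  parcels <- normalize_parcels(parcels)
  if (sum(parcels$area_ha) > land_area_ha * (1 + 1e-9)) {
    phos_error(sprintf("parcel areas of %s exceed catchment area",
                       catchment_id), "domain_error")
  }
  if (urban_population < 0 || riparian_septic_population < 0) {
    phos_error("populations must be non-negative", "domain_error")
  }
  extra_sources <- normalize_extras(extra_sources)
  if (precip_mm < 0 || pet_mm < 0) {
    phos_error("precip_mm and pet_mm must be non-negative", "domain_error")
  }
  if (runoff_coeff < 0) {
    phos_error("runoff_coeff must be non-negative", "domain_error")
  }
  if (!is.null(lake) && !inherits(lake, "water_body")) {
    phos_error("lake must be a water_body or NULL", "domain_error")
  }
  structure(list(catchment_id = catchment_id,
                 downstream_id = as.character(downstream_id),
                 land_area_ha = as.numeric(land_area_ha),
                 parcels = parcels,
                 urban_population = as.numeric(urban_population),
                 riparian_septic_population = as.numeric(riparian_septic_population),
                 extra_sources = extra_sources,
                 precip_mm = as.numeric(precip_mm),
                 pet_mm = as.numeric(pet_mm),
                 runoff_coeff = as.numeric(runoff_coeff),
                 lake = lake),
            class = "sub_catchment")
}

#' Assemble sub-catchments into a drainage network
#'
#' Downstream links must form a forest of directed trees (out-degree at most
#' one, no cycles) and every `downstream_id` must name a catchment in the
#' network.  Optional per-waterbody WFD breakpoints travel with the network.
#'
#' @param catchments A list of [sub_catchment()] objects.
#' @param breakpoints Optional data.frame of WFD class boundaries with
#'   columns `waterbody_id`, `hg`, `gm`, `mp`, `pb` (ug P/l, strictly
#'   increasing within each row).
#' @return A list of class `"catchment_network"` with elements `catchments`
#'   (named by catchment_id) and `breakpoints`.
#' @export
catchment_network <- function(catchments, breakpoints = NULL) {
  if (inherits(catchments, "sub_catchment")) catchments <- list(catchments)
  if (!length(catchments) ||
      !all(vapply(catchments, inherits, TRUE, "sub_catchment"))) {
    phos_error("catchments must be a non-empty list of sub_catchment objects",
               "domain_error")
  }
  ids <- vapply(catchments, `[[`, "", "catchment_id")
  if (anyDuplicated(ids)) {
    phos_error("duplicate catchment_id in network", "network_error")
  }
  names(catchments) <- ids
  down <- vapply(catchments, `[[`, "", "downstream_id")
  linked <- !is.na(down)
  unresolved <- down[linked][!(down[linked] %in% ids)]
  if (length(unresolved)) {
    phos_error(sprintf("downstream_id does not resolve: %s",
                       paste(sQuote(unique(unresolved)), collapse = ", ")),
               "network_error")
  }
  if (any(down[linked] == ids[linked])) {
    phos_error("catchment cannot drain to itself", "network_error")
  }
  net <- structure(list(catchments = catchments,
                        breakpoints = validate_breakpoints(breakpoints)),
                   class = "catchment_network")
  topological_order(net)  # errors on cycles, naming an edge
  net
}

validate_breakpoints <- function(breakpoints) {
  if (is.null(breakpoints)) return(NULL)
  need <- c("waterbody_id", "hg", "gm", "mp", "pb")
  if (!is.data.frame(breakpoints) || !all(need %in% names(breakpoints))) {
    phos_error("breakpoints need columns waterbody_id, hg, gm, mp, pb",
               "config_error")
  }
  vals <- as.matrix(breakpoints[, c("hg", "gm", "mp", "pb")])
  if (any(is.na(vals)) || any(vals <= 0) ||
      any(t(apply(vals, 1, diff)) <= 0)) {
    phos_error("breakpoints must be positive and strictly increasing",
               "config_error")
  }
  breakpoints
}

#' @export
print.catchment_network <- function(x, ...) {
  n <- length(x$catchments)
  lakes <- sum(vapply(x$catchments, function(s) !is.null(s$lake), TRUE))
  outlets <- sum(vapply(x$catchments, function(s) is.na(s$downstream_id), TRUE))
  cat(sprintf("catchment_network: %d sub-catchment%s, %d lake%s, %d outlet%s\n",
              n, if (n == 1) "" else "s", lakes, if (lakes == 1) "" else "s",
              outlets, if (outlets == 1) "" else "s"))
  invisible(x)
}

#' Topological order of a catchment network
#'
#' Orders sub-catchments so that every node appears after all nodes that
#' drain into it (headwaters first, outlets last).  A cycle in the downstream
#' links is reported as an error naming one offending edge.
#'
#' @param network A [catchment_network()] (or a bare list of sub_catchments
#'   during validation).
#' @return Character vector of catchment ids in upstream-to-downstream order.
#' @export
topological_order <- function(network) {
  catchments <- if (inherits(network, "catchment_network")) {
    network$catchments
  } else {
    network
  }
  ids <- names(catchments)
  down <- vapply(catchments, `[[`, "", "downstream_id")
  edges <- cbind(ids[!is.na(down)], down[!is.na(down)])
  if (nrow(edges) == 0) return(ids)
  g <- igraph::graph_from_data_frame(as.data.frame(edges),
                                     directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (!igraph::is_dag(g)) {
    # out-degree <= 1: chase downstream pointers to name a cycle edge
    for (start in ids) {
      seen <- character()
      cur <- start
      while (!is.na(down[[cur]])) {
        nxt <- down[[cur]]
        if (nxt %in% c(seen, cur)) {
          phos_error(sprintf("cycle in downstream links at edge %s -> %s",
                             cur, nxt), "network_error")
        }
        seen <- c(seen, cur)
        cur <- nxt
      }
    }
    phos_error("downstream links contain a cycle", "network_error")
  }
  as.character(igraph::topo_sort(g, mode = "out")$name)
}
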