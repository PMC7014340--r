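#' Annual diffuse phosphorus load from land-cover parcels
#'
#' Each parcel contributes `area_ha * EC(category, slope, setting)` kg P/yr,
#' where EC is the export coefficient in kg P/ha/yr.  The load is additive
#' over parcels and linear in parcel area.
#'
#' @param parcels data.frame with columns `landcover`, `slope_degrees` (or
#'   `slope_class`), `area_ha`.
#' @param ec An [ec_table()].
#' @param setting Which coefficient column to use: `"median"` (default),
#'   `"min"` or `"max"`.
#' @return Total load in kg P/yr.
#' @examples
#' ec <- default_export_coefficients()
#' land_load(data.frame(landcover = "Arable", slope_degrees = 2,
#'                      area_ha = 100), ec)
#' @export
land_load <- function(parcels, ec = default_export_coefficients(),
                      setting = c("median", "min", "max")) {
  setting <- match.arg(setting)
  parcels <- normalize_parcels(parcels)
  if (nrow(parcels) == 0) return(0)
  coef <- ec_lookup(ec, parcels$landcover, parcels$slope_class, setting)
  sum(parcels$area_ha * coef)
}

#' Population-derived phosphorus loads
#'
#' The urban population is assumed to discharge through waste-water treatment
#' works at the urban per-capita rate; only the rural population on septic
#' tanks within the riparian zone contributes at the septic rate.
#'
#' @param urban_population,riparian_septic_population Person counts, >= 0.
#' @param rates A [per_capita_rates()].
#' @return Named numeric `c(urban = ..., septic = ...)` in kg P/yr.
#' @export
population_loads <- function(urban_population, riparian_septic_population,
                             rates = per_capita_rates()) {
  if (urban_population < 0 || riparian_septic_population < 0) {
    phos_error("populations must be non-negative", "domain_error")
  }
  c(urban = urban_population * rates$urban,
    septic = riparian_septic_population * rates$septic)
}

#' Total load and per-source breakdown of additive extra sources
#'
#' Extra sources (fish farms, cage aquaculture, roosting birds, atmospheric
#' deposition, other) enter the budget as plain additive annual loads.
#' Entries of type `wwtw_override` are excluded from the sum returned here:
#' they replace the per-capita urban term instead (see [local_sources()]).
#'
#' @param extra_sources data.frame with columns `source_type`, `load_kg_yr`.
#' @return List with `total` (kg P/yr) and `by_source` (named numeric,
#'   summed by source type, overrides excluded).
#' @export
extra_source_load <- function(extra_sources) {
  extras <- normalize_extras(extra_sources)
  extras <- extras[extras$source_type != "wwtw_override", , drop = FALSE]
  if (nrow(extras) == 0) {
    return(list(total = 0, by_source = stats::setNames(numeric(0), character(0))))
  }
  by_source <- tapply(extras$load_kg_yr, extras$source_type, sum)
  by_source <- stats::setNames(as.numeric(by_source), names(by_source))
  list(total = sum(by_source), by_source = by_source)
}

#' Source apportionment of an annual phosphorus budget
#'
#' @param loads Named numeric vector of annual loads (kg P/yr) by source.
#' @return A list of class `"source_apportionment"` with `loads`, `total`
#'   and `shares` (percentages summing to 100 when the total is positive).
#' @export
source_apportionment <- function(loads) {
  if (any(loads < 0)) phos_error("loads must be non-negative", "domain_error")
  total <- sum(loads)
  shares <- if (total > 0) 100 * loads / total else loads * 0
  structure(list(loads = loads, total = total, shares = shares),
            class = "source_apportionment")
}

#' @export
print.source_apportionment <- function(x, ...) {
  cat(sprintf("annual TP load: %.1f kg P/yr\n", x$total))
  for (nm in names(x$loads)) {
    cat(sprintf("  %-12s %10.1f kg/yr  (%5.1f%%)\n", nm, x$loads[[nm]],
                x$shares[[nm]]))
  }
  invisible(x)
}

#' Local (within-catchment) phosphorus sources of one sub-catchment
#'
#' Combines the land-cover, population and extra-source loads of a single
#' sub-catchment, without any upstream contribution.  If the catchment
#' carries one or more `wwtw_override` extra sources, their summed load
#' replaces the per-capita urban term (used where actual treatment-works
#' discharge data supersede the population estimate, including works that
#' export effluent out of the catchment, where the override is zero).
#'
#' @param sc A [sub_catchment()].
#' @param ec An [ec_table()].
#' @param rates A [per_capita_rates()].
#' @param setting Export-coefficient setting, `"median"`, `"min"` or `"max"`.
#' @return A [source_apportionment()] with components `land`, `urban`,
#'   `septic` and one entry per extra source type present.
#' @export
local_sources <- function(sc, ec = default_export_coefficients(),
                          rates = per_capita_rates(),
                          setting = c("median", "min", "max")) {
  setting <- match.arg(setting)
  stopifnot(inherits(sc, "sub_catchment"))
  land <- land_load(sc$parcels, ec, setting)
  pop <- population_loads(sc$urban_population, sc$riparian_septic_population,
                          rates)
  override <- sc$extra_sources$source_type == "wwtw_override"
  urban <- if (any(override)) {
    sum(sc$extra_sources$load_kg_yr[override])
  } else {
    pop[["urban"]]
  }
  extras <- extra_source_load(sc$extra_sources)
  loads <- c(land = land, urban = urban, septic = pop[["septic"]],
             extras$by_source)
  source_apportionment(loads)
}
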