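#' Scenario change records
#'
#' Constructors for the typed change records accepted by [apply_scenario()]:
#' \describe{
#'   \item{`sc_land_transfer`}{Move `area_ha` of land from one category to
#'     another within a catchment, slope bands preserved.  `from = NULL`
#'     reassigns every parcel to `to` (area conserved).}
#'   \item{`sc_extra_source`}{Add an extra source (fish farm, birds,
#'     deposition, `wwtw_override`, ...) with the given annual load.}
#'   \item{`sc_remove_extra`}{Remove all extra sources of one type.}
#'   \item{`sc_climate_scale`}{Multiply precipitation and/or PET by factors,
#'     in one catchment or (default) network-wide.}
#'   \item{`sc_population`}{Set urban and/or riparian septic populations.}
#'   \item{`sc_per_capita`}{Override the per-capita urban/septic rates for
#'     runs on the scenario network.}
#' }
#'
#' @param catchment_id Target catchment id (`NULL` for network-wide where
#'   supported).
#' @param from,to Land-cover categories.
#' @param area_ha Area to transfer, ha (ignored when `from = NULL`).
#' @param source_type Extra-source type, see [sub_catchment()].
#' @param load_kg_yr Annual load, kg P/yr.
#' @param precip_factor,pet_factor Positive scaling factors.
#' @param urban,septic Population counts (`sc_population`) or per-capita
#'   rates in kg P/person/yr (`sc_per_capita`); `NULL` leaves unchanged.
#' @return A scenario change record (list with class `"scenario_change"`).
#' @name scenario_changes
NULL

sc_change <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "scenario_change")
}

#' @rdname scenario_changes
#' @export
sc_land_transfer <- function(catchment_id, from = NULL, to, area_ha = NULL) {
  if (!to %in% landCoverCategories()) {
    phos_error(sprintf("unknown land-cover category: %s", sQuote(to)),
               "lookup_error")
  }
  if (!is.null(from)) {
    if (!from %in% landCoverCategories()) {
      phos_error(sprintf("unknown land-cover category: %s", sQuote(from)),
                 "lookup_error")
    }
    if (is.null(area_ha) || area_ha < 0) {
      phos_error("area_ha must be a non-negative number", "domain_error")
    }
  }
  sc_change("land_transfer", catchment_id = catchment_id, from = from,
            to = to, area_ha = area_ha)
}

#' @rdname scenario_changes
#' @export
sc_extra_source <- function(catchment_id, source_type, load_kg_yr) {
  if (!source_type %in% extraSourceTypes()) {
    phos_error(sprintf("unknown extra-source type: %s", sQuote(source_type)),
               "domain_error")
  }
  if (load_kg_yr < 0) phos_error("load must be non-negative", "domain_error")
  sc_change("extra_source", catchment_id = catchment_id,
            source_type = source_type, load_kg_yr = load_kg_yr)
}

#' @rdname scenario_changes
#' @export
sc_remove_extra <- function(catchment_id, source_type) {
  sc_change("remove_extra", catchment_id = catchment_id,
            source_type = source_type)
}

#' @rdname scenario_changes
#' @export
sc_climate_scale <- function(precip_factor = 1, pet_factor = 1,
                             catchment_id = NULL) {
  if (precip_factor <= 0 || pet_factor <= 0) {
    phos_error("climate scaling factors must be positive", "domain_error")
  }
  sc_change("climate_scale", catchment_id = catchment_id,
            precip_factor = precip_factor, pet_factor = pet_factor)
}

#' @rdname scenario_changes
#' @export
sc_population <- function(catchment_id, urban = NULL, septic = NULL) {
  sc_change("population", catchment_id = catchment_id, urban = urban,
            septic = septic)
}

#' @rdname scenario_changes
#' @export
sc_per_capita <- function(urban = NULL, septic = NULL) {
  sc_change("per_capita", catchment_id = NULL, urban = urban, septic = septic)
}

resolve_targets <- function(network, catchment_id) {
  if (is.null(catchment_id)) return(names(network$catchments))
  if (!catchment_id %in% names(network$catchments)) {
    phos_error(sprintf("scenario references unknown catchment: %s",
                       sQuote(catchment_id)), "domain_error")
  }
  catchment_id
}

#' Apply a scenario to a catchment network
#'
#' Returns a modified copy of the network; the baseline network is never
#' altered, so baseline runs remain bit-reproducible after any number of
#' scenario runs.  Per-capita rate overrides are carried as the
#' `"per_capita_override"` attribute of the returned network, which
#' [route_network()] and [run_pipeline()] honour.
#'
#' @param network A [catchment_network()].
#' @param changes A single change record or a list of records (see
#'   [scenario_changes]).
#' @return A modified [catchment_network()].
#' @export
apply_scenario <- function(network, changes) {
  stopifnot(inherits(network, "catchment_network"))
  if (inherits(changes, "scenario_change")) changes <- list(changes)
  if (!all(vapply(changes, inherits, TRUE, "scenario_change"))) {
    phos_error("changes must be scenario_change records", "domain_error")
  }
  net <- network
  for (ch in changes) {
    targets <- resolve_targets(net, ch$catchment_id)
    for (id in targets) {
      sc <- net$catchments[[id]]
      sc <- switch(ch$type,
        land_transfer = scenario_land_transfer(sc, ch),
        extra_source = {
          sc$extra_sources <- rbind(sc$extra_sources,
                                    data.frame(source_type = ch$source_type,
                                               load_kg_yr = ch$load_kg_yr))
          sc
        },
        remove_extra = {
          keep <- sc$extra_sources$source_type != ch$source_type
          sc$extra_sources <- sc$extra_sources[keep, , drop = FALSE]
          rownames(sc$extra_sources) <- NULL
          sc
        },
        climate_scale = {
          sc$precip_mm <- sc$precip_mm * ch$precip_factor
          sc$pet_mm <- sc$pet_mm * ch$pet_factor
          sc
        },
        population = {
          if (!is.null(ch$urban)) sc$urban_population <- ch$urban
          if (!is.null(ch$septic)) sc$riparian_septic_population <- ch$septic
          sc
        },
        per_capita = sc,
        phos_error(sprintf("unknown scenario change type %s", ch$type),
                   "domain_error"))
      net$catchments[[id]] <- sc
    }
    if (ch$type == "per_capita") {
      ov <- attr(net, "per_capita_override")
      if (is.null(ov)) ov <- list()
      if (!is.null(ch$urban)) ov$urban <- ch$urban
      if (!is.null(ch$septic)) ov$septic <- ch$septic
      attr(net, "per_capita_override") <- ov
    }
  }
  net
}

scenario_land_transfer <- function(sc, ch) {
  p <- sc$parcels
  if (is.null(ch$from)) {
    # reassign every parcel to the target category, areas and slopes kept
    p$landcover <- rep(ch$to, nrow(p))
    sc$parcels <- p
    return(sc)
  }
  idx <- which(p$landcover == ch$from)
  avail <- sum(p$area_ha[idx])
  if (ch$area_ha > avail + 1e-9) {
    phos_error(sprintf("cannot transfer %.1f ha of %s in %s: only %.1f ha present",
                       ch$area_ha, sQuote(ch$from), sc$catchment_id, avail),
               "domain_error")
  }
  remaining <- ch$area_ha
  new_rows <- NULL
  for (i in idx) {
    if (remaining <= 0) break
    take <- min(p$area_ha[i], remaining)
    p$area_ha[i] <- p$area_ha[i] - take
    new_rows <- rbind(new_rows,
                      data.frame(landcover = ch$to,
                                 slope_class = p$slope_class[i],
                                 area_ha = take))
    remaining <- remaining - take
  }
  p <- p[p$area_ha > 0, , drop = FALSE]
  if (!is.null(new_rows)) {
    common <- intersect(names(p), names(new_rows))
    p <- rbind(p[, common, drop = FALSE], new_rows[, common, drop = FALSE])
  }
  rownames(p) <- NULL
  sc$parcels <- p
  sc
}

#' Differences between a baseline and a scenario run
#'
#' @param baseline,scenario Results tables from [run_pipeline()] over the
#'   same set of waterbodies.
#' @return A list of class `"scenario_diff"`: `deltas` (per waterbody:
#'   delta_load_kg_yr, delta_conc_ugl, class_from, class_to, `changed`) and
#'   `transitions` (the subset with a class change).
#' @export
diff_report <- function(baseline, scenario) {
  if (!setequal(baseline$waterbody_id, scenario$waterbody_id) ||
      nrow(baseline) != nrow(scenario)) {
    phos_error("baseline and scenario cover different waterbody sets",
               "domain_error")
  }
  b <- baseline[order(baseline$waterbody_id), ]
  s <- scenario[order(scenario$waterbody_id), ]
  deltas <- data.frame(waterbody_id = b$waterbody_id,
                       delta_load_kg_yr = s$load_total - b$load_total,
                       delta_conc_ugl = s$tp_lake_ugl - b$tp_lake_ugl,
                       class_from = b$wfd_class,
                       class_to = s$wfd_class,
                       changed = b$wfd_class != s$wfd_class,
                       stringsAsFactors = FALSE)
  structure(list(deltas = deltas,
                 transitions = deltas[deltas$changed, , drop = FALSE]),
            class = "scenario_diff")
}

#' @export
print.scenario_diff <- function(x, ...) {
  cat(sprintf("scenario diff over %d waterbodies; %d class transition(s)\n",
              nrow(x$deltas), nrow(x$transitions)))
  if (nrow(x$transitions)) print(x$transitions, row.names = FALSE)
  invisible(x)
}
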