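#' Model configuration
#'
#' Collects the tunable constants of a model run.  Any entry can be
#' overridden from a YAML key-value file via [read_config()].
#'
#' @param ec_setting Export-coefficient setting: "median", "min" or "max".
#' @param retention Lake retention mode passed to [route_network()].
#' @param rates A [per_capita_rates()].
#' @param oecd An [oecd_parameters()].
#' @param amber_fraction Amber-band width for [traffic_light()].
#' @param target_boundary Boundary assessed by the traffic light.
#' @param discharge_multiplier Scalar on all local discharges.
#' @param ec Optional [ec_table()] replacing the packaged defaults.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(ec_setting = "median", retention = "all_lakes",
                         rates = per_capita_rates(),
                         oecd = oecd_parameters(), amber_fraction = 0.10,
                         target_boundary = "gm", discharge_multiplier = 1,
                         ec = NULL) {
  ec_setting <- match.arg(ec_setting, c("median", "min", "max"))
  retention <- match.arg(retention, c("all_lakes", "terminal_only"))
  structure(list(ec_setting = ec_setting, retention = retention,
                 rates = rates, oecd = oecd,
                 amber_fraction = amber_fraction,
                 target_boundary = target_boundary,
                 discharge_multiplier = discharge_multiplier, ec = ec),
            class = "model_config")
}

#' Read a configuration file
#'
#' YAML key-value file; recognised keys are `ec_setting`, `retention`,
#' `urban_per_capita`, `septic_per_capita`, `shallow_a`, `shallow_b`,
#' `combined_a`, `combined_b`, `depth_threshold`, `amber_fraction`,
#' `target_boundary`, `discharge_multiplier` and `ec_table` (path to a CSV
#' read with [read_export_coefficients()]).  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param base A [model_config()] supplying values for keys not in the file.
#' @return A [model_config()].
#' @export
read_config <- function(path, base = model_config()) {
  if (!file.exists(path)) {
    phos_error(sprintf("config file not found: %s", path), "config_error")
  }
  raw <- yaml::read_yaml(path)
  known <- c("ec_setting", "retention", "urban_per_capita",
             "septic_per_capita", "shallow_a", "shallow_b", "combined_a",
             "combined_b", "depth_threshold", "amber_fraction",
             "target_boundary", "discharge_multiplier", "ec_table")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    phos_error(sprintf("unknown config key: %s",
                       paste(sQuote(bad), collapse = ", ")), "config_error")
  }
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  o <- base$oecd
  model_config(
    ec_setting = pick("ec_setting", base$ec_setting),
    retention = pick("retention", base$retention),
    rates = per_capita_rates(pick("urban_per_capita", base$rates$urban),
                             pick("septic_per_capita", base$rates$septic)),
    oecd = oecd_parameters(pick("shallow_a", o$shallow[["a"]]),
                           pick("shallow_b", o$shallow[["b"]]),
                           pick("combined_a", o$combined[["a"]]),
                           pick("combined_b", o$combined[["b"]]),
                           pick("depth_threshold", o$depth_threshold)),
    amber_fraction = pick("amber_fraction", base$amber_fraction),
    target_boundary = pick("target_boundary", base$target_boundary),
    discharge_multiplier = pick("discharge_multiplier",
                                base$discharge_multiplier),
    ec = if (!is.null(raw$ec_table)) {
      read_export_coefficients(raw$ec_table)
    } else {
      base$ec
    })
}

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, "")
}

#' Write a catchment network as a CSV bundle
#'
#' Writes `catchments.csv`, `parcels.csv`, `lakes.csv`, `breakpoints.csv`
#' and `extra_sources.csv` (the last two only when present) into a
#' directory.  Numeric columns are written with full precision so that
#' [read_bundle()] reproduces the network exactly.
#'
#' @param network A [catchment_network()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(network, dir) {
  stopifnot(inherits(network, "catchment_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- network$catchments
  catch <- data.frame(
    catchment_id = names(cs),
    downstream_id = vapply(cs, function(s) {
      if (is.na(s$downstream_id)) "" else s$downstream_id
    }, ""),
    land_area_ha = fmt_num(vapply(cs, `[[`, 0, "land_area_ha")),
    urban_population = fmt_num(vapply(cs, `[[`, 0, "urban_population")),
    riparian_septic_population =
      fmt_num(vapply(cs, `[[`, 0, "riparian_septic_population")),
    precip_mm = fmt_num(vapply(cs, `[[`, 0, "precip_mm")),
    pet_mm = fmt_num(vapply(cs, `[[`, 0, "pet_mm")),
    runoff_coeff = fmt_num(vapply(cs, `[[`, 0, "runoff_coeff")),
    stringsAsFactors = FALSE)
  utils::write.csv(catch, file.path(dir, "catchments.csv"),
                   row.names = FALSE)

  parcels <- do.call(rbind, lapply(cs, function(s) {
    if (nrow(s$parcels) == 0) return(NULL)
    data.frame(catchment_id = s$catchment_id,
               landcover = s$parcels$landcover,
               slope_class = s$parcels$slope_class,
               area_ha = fmt_num(s$parcels$area_ha),
               stringsAsFactors = FALSE)
  }))
  if (is.null(parcels)) {
    parcels <- data.frame(catchment_id = character(),
                          landcover = character(),
                          slope_class = character(), area_ha = character())
  }
  utils::write.csv(parcels, file.path(dir, "parcels.csv"), row.names = FALSE)

  lakes <- do.call(rbind, lapply(cs, function(s) {
    if (is.null(s$lake)) return(NULL)
    data.frame(waterbody_id = s$lake$waterbody_id,
               catchment_id = s$catchment_id,
               surface_area_km2 = fmt_num(s$lake$surface_area_km2),
               mean_depth_m = fmt_num(s$lake$mean_depth_m),
               volume_m3 = fmt_num(s$lake$volume_m3),
               stringsAsFactors = FALSE)
  }))
  if (is.null(lakes)) {
    lakes <- data.frame(waterbody_id = character(),
                        catchment_id = character(),
                        surface_area_km2 = character(),
                        mean_depth_m = character(), volume_m3 = character())
  }
  utils::write.csv(lakes, file.path(dir, "lakes.csv"), row.names = FALSE)

  extras <- do.call(rbind, lapply(cs, function(s) {
    if (nrow(s$extra_sources) == 0) return(NULL)
    data.frame(catchment_id = s$catchment_id,
               source_type = s$extra_sources$source_type,
               load_kg_yr = fmt_num(s$extra_sources$load_kg_yr),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(extras)) {
    utils::write.csv(extras, file.path(dir, "extra_sources.csv"),
                     row.names = FALSE)
  }
  if (!is.null(network$breakpoints)) {
    bp <- network$breakpoints
    out <- data.frame(waterbody_id = bp$waterbody_id, hg = fmt_num(bp$hg),
                      gm = fmt_num(bp$gm), mp = fmt_num(bp$mp),
                      pb = fmt_num(bp$pb), stringsAsFactors = FALSE)
    utils::write.csv(out, file.path(dir, "breakpoints.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

read_bundle_csv <- function(dir, file, required_cols, optional = FALSE) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    if (optional) return(NULL)
    phos_error(sprintf("required bundle file missing: %s", path),
               "config_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    phos_error(sprintf("%s: missing column(s) %s", file,
                       paste(sQuote(missing), collapse = ", ")),
               "config_error")
  }
  df
}

num_col <- function(df, col, file) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & nzchar(df[[col]]))
  if (length(bad)) {
    phos_error(sprintf("%s line %d: column %s is not numeric", file,
                       bad[1] + 1L, sQuote(col)), "config_error")
  }
  x
}

#' Read a catchment network from a CSV bundle
#'
#' Expects `catchments.csv`, `parcels.csv` and `lakes.csv` (the latter two
#' may be empty), plus optional `breakpoints.csv` and `extra_sources.csv`,
#' in the layout written by [write_bundle()].  All type invariants are
#' validated at load; violations are reported with the offending file (and
#' line where known).
#'
#' @param dir Bundle directory.
#' @return A [catchment_network()].
#' @export
read_bundle <- function(dir) {
  catch <- read_bundle_csv(dir, "catchments.csv",
                           c("catchment_id", "downstream_id",
                             "land_area_ha", "precip_mm", "pet_mm"))
  parcels <- read_bundle_csv(dir, "parcels.csv",
                             c("catchment_id", "landcover", "area_ha"),
                             optional = TRUE)
  lakes <- read_bundle_csv(dir, "lakes.csv",
                           c("waterbody_id", "catchment_id",
                             "surface_area_km2", "mean_depth_m"),
                           optional = TRUE)
  extras <- read_bundle_csv(dir, "extra_sources.csv",
                            c("catchment_id", "source_type", "load_kg_yr"),
                            optional = TRUE)
  bps <- read_bundle_csv(dir, "breakpoints.csv",
                         c("waterbody_id", "hg", "gm", "mp", "pb"),
                         optional = TRUE)

  opt_num <- function(df, col, default) {
    if (!is.null(df[[col]])) num_col(df, col, "catchments.csv") else default
  }
  n <- nrow(catch)
  land_area <- num_col(catch, "land_area_ha", "catchments.csv")
  precip <- num_col(catch, "precip_mm", "catchments.csv")
  pet <- num_col(catch, "pet_mm", "catchments.csv")
  urb <- opt_num(catch, "urban_population", rep(0, n))
  sep <- opt_num(catch, "riparian_septic_population", rep(0, n))
  rc <- opt_num(catch, "runoff_coeff", rep(1, n))

  if (!is.null(parcels) && nrow(parcels)) {
    parcels$area_ha <- num_col(parcels, "area_ha", "parcels.csv")
    if ("slope_degrees" %in% names(parcels)) {
      parcels$slope_degrees <- num_col(parcels, "slope_degrees",
                                       "parcels.csv")
    }
  }
  if (!is.null(lakes) && nrow(lakes)) {
    for (col in c("surface_area_km2", "mean_depth_m")) {
      lakes[[col]] <- num_col(lakes, col, "lakes.csv")
    }
    lakes$volume_m3 <- if ("volume_m3" %in% names(lakes)) {
      suppressWarnings(as.numeric(lakes$volume_m3))
    } else {
      NA_real_
    }
    if (anyDuplicated(lakes$catchment_id)) {
      phos_error("lakes.csv: more than one lake per catchment",
                 "config_error")
    }
  }
  if (!is.null(extras) && nrow(extras)) {
    extras$load_kg_yr <- num_col(extras, "load_kg_yr", "extra_sources.csv")
  }
  if (!is.null(bps) && nrow(bps)) {
    for (col in c("hg", "gm", "mp", "pb")) {
      bps[[col]] <- num_col(bps, col, "breakpoints.csv")
    }
  }

  catchments <- lapply(seq_len(n), function(i) {
    id <- catch$catchment_id[i]
    p <- if (!is.null(parcels) && nrow(parcels)) {
      parcels[parcels$catchment_id == id,
              setdiff(names(parcels), "catchment_id"), drop = FALSE]
    } else {
      NULL
    }
    ex <- if (!is.null(extras) && nrow(extras)) {
      extras[extras$catchment_id == id,
             c("source_type", "load_kg_yr"), drop = FALSE]
    } else {
      NULL
    }
    lk <- NULL
    if (!is.null(lakes) && nrow(lakes)) {
      j <- which(lakes$catchment_id == id)
      if (length(j) == 1) {
        lk <- water_body(lakes$waterbody_id[j], lakes$surface_area_km2[j],
                         lakes$mean_depth_m[j], lakes$volume_m3[j])
      }
    }
    sub_catchment(catchment_id = id,
                  downstream_id = catch$downstream_id[i],
                  land_area_ha = land_area[i], parcels = p,
                  urban_population = urb[i],
                  riparian_septic_population = sep[i], extra_sources = ex,
                  precip_mm = precip[i], pet_mm = pet[i],
                  runoff_coeff = rc[i], lake = lk)
  })
  catchment_network(catchments, breakpoints = bps)
}

#' Run the full load-concentration-status pipeline
#'
#' Routes the network, predicts in-lake concentrations, classifies every
#' standing water against its WFD breakpoints and trophic thresholds,
#' assesses traffic-light proximity to the target boundary, and computes
#' headroom to the current class boundary.  Output is deterministic for
#' fixed inputs and ordered by waterbody id.
#'
#' @param network A [catchment_network()] (breakpoints attached or supplied
#'   in `breakpoints`).
#' @param config A [model_config()].
#' @param breakpoints Optional breakpoint table overriding the network's.
#' @return A data.frame with one row per standing water: waterbody and
#'   catchment ids, load by source (land, urban, septic, extra, upstream),
#'   total load, discharge, residence time, inflow and in-lake TP
#'   concentrations, WFD class, trophic class, traffic light, headroom and
#'   its boundary-exceeded flag.  Classification columns are `NA` for lakes
#'   without breakpoints.
#' @export
run_pipeline <- function(network, config = model_config(),
                         breakpoints = NULL) {
  stopifnot(inherits(network, "catchment_network"))
  bp_tab <- if (!is.null(breakpoints)) {
    validate_breakpoints(breakpoints)
  } else {
    network$breakpoints
  }
  ec <- if (is.null(config$ec)) default_export_coefficients() else config$ec
  routed <- route_network(network, ec = ec, rates = config$rates,
                          oecd = config$oecd, setting = config$ec_setting,
                          retention = config$retention,
                          discharge_multiplier = config$discharge_multiplier)
  rows <- lapply(routed, function(node) {
    sc <- network$catchments[[node$catchment_id]]
    if (is.null(sc$lake)) return(NULL)
    loads <- node$apportionment$loads
    extra <- sum(loads[setdiff(names(loads),
                               c("land", "urban", "septic", "upstream"))])
    q <- node$hydrology$outflow_m3_yr
    pred <- node$lake
    total <- node$apportionment$total
    row <- data.frame(waterbody_id = sc$lake$waterbody_id,
                      catchment_id = node$catchment_id,
                      load_land = loads[["land"]],
                      load_urban = loads[["urban"]],
                      load_septic = loads[["septic"]],
                      load_extra = extra,
                      load_upstream = loads[["upstream"]],
                      load_total = total,
                      discharge_m3_yr = q,
                      residence_yr = pred$tau,
                      tp_in_ugl = pred$tp_in,
                      tp_lake_ugl = pred$tp_lake,
                      wfd_class = NA_character_,
                      trophic = trophic_class(pred$tp_lake),
                      traffic_light = NA_character_,
                      headroom_kg_yr = NA_real_,
                      boundary_exceeded = NA,
                      stringsAsFactors = FALSE)
    bp <- NULL
    if (!is.null(bp_tab)) {
      j <- which(bp_tab$waterbody_id == sc$lake$waterbody_id)
      if (length(j) == 1) bp <- bp_tab[j, , drop = FALSE]
    }
    if (!is.null(bp)) {
      row$wfd_class <- wfd_status(pred$tp_lake, bp)
      row$traffic_light <- traffic_light(pred$tp_lake, bp,
                                         config$target_boundary,
                                         config$amber_fraction)
      head <- headroom_load(total, q, sc$lake, bp, config$oecd)
      row$headroom_kg_yr <- head$headroom_kg_yr
      row$boundary_exceeded <- head$boundary_exceeded
    }
    row
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- data.frame(waterbody_id = character(), catchment_id = character(),
                      load_land = numeric(), load_urban = numeric(),
                      load_septic = numeric(), load_extra = numeric(),
                      load_upstream = numeric(), load_total = numeric(),
                      discharge_m3_yr = numeric(), residence_yr = numeric(),
                      tp_in_ugl = numeric(), tp_lake_ugl = numeric(),
                      wfd_class = character(), trophic = character(),
                      traffic_light = character(),
                      headroom_kg_yr = numeric(),
                      boundary_exceeded = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$waterbody_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a results table with fixed formatting
#'
#' Concentrations are written to one decimal place and loads to one decimal
#' place, giving byte-identical files for identical runs.
#'
#' @param results A results table from [run_pipeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results
  load_cols <- grep("^(load_|headroom_)", names(out), value = TRUE)
  for (col in c(load_cols, "tp_in_ugl", "tp_lake_ugl")) {
    out[[col]] <- sprintf("%.1f", results[[col]])
  }
  out$discharge_m3_yr <- sprintf("%.0f", results$discharge_m3_yr)
  out$residence_yr <- sprintf("%.3f", results$residence_yr)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
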