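#' @keywords internal
"_PACKAGE"

# Condition helper: classed errors so callers/tests can discriminate failure
# modes (domain_error, lookup_error, config_error, network_error, no_flushing).
phos_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phoscade_error")))
}

#' Land-cover categories of the export-coefficient registry
#'
#' The closed registry of land-cover categories for which phosphorus export
#' coefficients are defined.  Parcel tables referring to any other category
#' are rejected at load time.
#'
#' @return Character vector of category names.
#' @export
landCoverCategories <- function() {
  c("Water",
    "Wetland",
    "Blanket bog & peatland",
    "Arable",
    "Improved grassland",
    "Coarse grassland, Smooth grassland, Heather all types, Bracken",
    "Cliffs",
    "Montane vegetation",
    "Low scrub",
    "Broadleaved woodland",
    "Mixed woodland, Open canopy young plantation",
    "Coniferous plantation",
    "Recently ploughed land",
    "Woodland recently felled",
    "Ripping",
    "Estuary, Salt marsh, Dune land, Maritime grasslands & heaths",
    "Airfields, Recreational land, Quarries, Other land, Road & rail",
    "Factories & urban")
}

#' Slope class levels
#'
#' @return Character vector `c("Low", "Medium", "High")`, in increasing order
#'   of steepness.  Low covers slopes of 0 to 4 degrees, Medium 4 to 13, High
#'   13 and above (lower-inclusive intervals, see [classify_slope()]).
#' @export
slopeClasses <- function() c("Low", "Medium", "High")

# Extra (non-land, non-population) point/diffuse source types.
# "wwtw_override" replaces the per-capita urban term rather than adding to it.
extraSourceTypes <- function() {
  c("fish_farm", "fish_cage", "birds", "deposition", "wwtw_override", "other")
}

#' Classify a slope in degrees into the Low/Medium/High export-coefficient band
#'
#' Intervals are half-open and lower-inclusive: Low is \[0, 4) degrees, Medium
#' \[4, 13), High \[13, Inf).  The band boundaries 4 and 13 therefore belong to
#' the steeper class.
#'
#' @param slope_degrees Numeric vector of slopes in degrees, all >= 0.
#' @return Character vector of slope classes.
#' @examples
#' classify_slope(c(0, 7, 13))
#' @export
classify_slope <- function(slope_degrees) {
  if (!is.numeric(slope_degrees) || any(is.na(slope_degrees))) {
    phos_error("slope_degrees must be numeric and non-missing", "domain_error")
  }
  if (any(slope_degrees < 0)) {
    phos_error("negative slope is not meaningful", "domain_error")
  }
  ifelse(slope_degrees < 4, "Low", ifelse(slope_degrees < 13, "Medium", "High"))
}

#' Construct and validate an export-coefficient table
#'
#' An export-coefficient table maps every (land-cover category, slope class)
#' pair to a minimum, median and maximum annual total-phosphorus export rate
#' in kg P/ha/yr.  The median values are the model defaults; the min/max
#' columns drive the export-coefficient sensitivity mode.
#'
#' @param df A data.frame with columns `category`, `slope_class`, `ec_min`,
#'   `ec_median`, `ec_max`.
#' @return The validated table with class `"ec_table"`.
#' @export
ec_table <- function(df) {
  need <- c("category", "slope_class", "ec_min", "ec_median", "ec_max")
  if (!all(need %in% names(df))) {
    phos_error(sprintf("export-coefficient table must have columns: %s",
                       paste(need, collapse = ", ")), "config_error")
  }
  bad <- setdiff(unique(df$category), landCoverCategories())
  if (length(bad)) {
    phos_error(sprintf("unknown land-cover category: %s",
                       paste(sQuote(bad), collapse = ", ")), "config_error")
  }
  if (!all(df$slope_class %in% slopeClasses())) {
    phos_error("slope_class must be Low, Medium or High", "config_error")
  }
  combos <- expand.grid(category = landCoverCategories(),
                        slope_class = slopeClasses(),
                        stringsAsFactors = FALSE)
  key <- paste(df$category, df$slope_class, sep = "\r")
  if (anyDuplicated(key)) {
    phos_error("duplicate (category, slope_class) rows", "config_error")
  }
  missing <- !(paste(combos$category, combos$slope_class, sep = "\r") %in% key)
  if (any(missing)) {
    phos_error(sprintf("export-coefficient table is missing %d (category, slope) pairs",
                       sum(missing)), "config_error")
  }
  vals <- as.matrix(df[, c("ec_min", "ec_median", "ec_max")])
  if (any(is.na(vals)) || any(vals < 0)) {
    phos_error("export coefficients must be non-negative and non-missing",
               "config_error")
  }
  if (any(df$ec_min > df$ec_median) || any(df$ec_median > df$ec_max)) {
    phos_error("export coefficients must satisfy min <= median <= max",
               "config_error")
  }
  df <- df[order(match(df$category, landCoverCategories()),
                 match(df$slope_class, slopeClasses())), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ec_table", "data.frame"))
}

#' Packaged default export-coefficient table
#'
#' Median coefficients for the 18 registry categories by slope band.  The
#' ranges are synthetic defaults (median divided/multiplied by 1.5, rounded to
#' 4 decimals on the minimum) anchored at the two documented extremes:
#' wetlands 0.02--0.15 kg/ha/yr across slope bands and grasslands on steep
#' slopes 0.08--0.15 kg/ha/yr.  Water, Wetland and Cliffs carry a single
#' slope-invariant coefficient; the zero-export categories (estuarine and
#' sealed/managed surfaces) are retained so that area accounting stays
#' complete.
#'
#' @return An [ec_table()].
#' @export
default_export_coefficients <- function() {
  path <- system.file("extdata", "export_coefficients.csv",
                      package = "phoscade", mustWork = TRUE)
  read_export_coefficients(path)
}

#' Read / write an export-coefficient table
#'
#' CSV with columns `category`, `slope_class`, `ec_min`, `ec_median`,
#' `ec_max`.  Writing and re-reading reproduces the table exactly.
#'
#' @param path File path.
#' @param tab An [ec_table()].
#' @return `read_export_coefficients` returns an [ec_table()];
#'   `write_export_coefficients` returns `path` invisibly.
#' @export
read_export_coefficients <- function(path) {
  if (!file.exists(path)) {
    phos_error(sprintf("export-coefficient file not found: %s", path),
               "config_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ec_table(df)
}

#' @rdname read_export_coefficients
#' @export
write_export_coefficients <- function(tab, path) {
  stopifnot(inherits(tab, "ec_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Vectorised coefficient lookup; errors name the offending category.
ec_lookup <- function(tab, category, slope_class,
                      setting = c("median", "min", "max")) {
  setting <- match.arg(setting)
  col <- paste0("ec_", setting)
  key <- paste(tab$category, tab$slope_class, sep = "\r")
  idx <- match(paste(category, slope_class, sep = "\r"), key)
  if (anyNA(idx)) {
    bad <- unique(category[is.na(idx)])
    phos_error(sprintf("no export coefficient for land-cover category: %s",
                       paste(sQuote(bad), collapse = ", ")), "lookup_error")
  }
  tab[[col]][idx]
}

#' Per-capita waste-water phosphorus load rates
#'
#' Annual total-phosphorus loss per person.  The urban rate applies to the
#' population whose waste water reaches surface waters through treatment
#' works (default 0.9125 kg P/person/yr); the septic rate applies to the
#' rural population on riparian septic tanks (default 0.25 kg P/person/yr).
#'
#' @param urban,septic Non-negative rates in kg P/person/yr.
#' @return A list of class `"per_capita_rates"`.
#' @export
per_capita_rates <- function(urban = 0.9125, septic = 0.25) {
  if (!is.numeric(urban) || !is.numeric(septic) || urban < 0 || septic < 0) {
    phos_error("per-capita rates must be non-negative numbers", "domain_error")
  }
  structure(list(urban = urban, septic = septic), class = "per_capita_rates")
}

#' OECD load-to-concentration model parameters
#'
#' The in-lake TP concentration is `a * (TP_in / (1 + sqrt(tau)))^b`, where
#' `TP_in` is the flow-weighted inflow concentration and `tau` the residence
#' time in years.  Two parameterisations are carried: one fitted to shallow
#' lakes and reservoirs (a = 1.02, b = 0.88) and one to the combined lake
#' data set (a = 1.55, b = 0.82).  The mean-depth threshold (default 3.0 m,
#' shallow at or below it) governs which pair a waterbody receives.
#'
#' @param shallow_a,shallow_b Shallow-lake multiplier and exponent.
#' @param combined_a,combined_b Combined-data-set multiplier and exponent.
#' @param depth_threshold Mean depth (m) at or below which the shallow pair
#'   is used.
#' @return A list of class `"oecd_parameters"`.
#' @export
oecd_parameters <- function(shallow_a = 1.02, shallow_b = 0.88,
                            combined_a = 1.55, combined_b = 0.82,
                            depth_threshold = 3.0) {
  vals <- c(shallow_a, shallow_b, combined_a, combined_b, depth_threshold)
  if (any(!is.finite(vals))) phos_error("non-finite parameter", "domain_error")
  if (shallow_a <= 0 || combined_a <= 0) {
    phos_error("multiplier a must be positive", "domain_error")
  }
  if (shallow_b <= 0 || shallow_b > 1 || combined_b <= 0 || combined_b > 1) {
    phos_error("exponent b must lie in (0, 1]", "domain_error")
  }
  if (depth_threshold <= 0) {
    phos_error("depth_threshold must be positive", "domain_error")
  }
  structure(list(shallow = c(a = shallow_a, b = shallow_b),
                 combined = c(a = combined_a, b = combined_b),
                 depth_threshold = depth_threshold),
            class = "oecd_parameters")
}

#' Packaged model defaults
#'
#' Convenience loader returning the default export-coefficient table,
#' per-capita rates and OECD parameter presets in one call.
#'
#' @return A list with elements `ec`, `rates`, `oecd`.
#' @export
load_defaults <- function() {
  list(ec = default_export_coefficients(),
       rates = per_capita_rates(),
       oecd = oecd_parameters())
}
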