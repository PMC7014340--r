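# Concentrations of every lake in a routed network, named by waterbody id.
routed_concentrations <- function(routed) {
  vals <- lapply(routed, function(node) {
    if (is.null(node$lake)) return(NULL)
    stats::setNames(node$lake$tp_lake,
                    network_lake_id(node))
  })
  unlist(vals)
}

network_lake_id <- function(node) {
  # routed nodes do not carry the water_body; key by catchment id, which is
  # unique and maps 1:1 to its lake
  node$catchment_id
}

#' Summary statistics used by the sensitivity report tables
#'
#' Minimum, 5th/10th percentiles, median, mean, 90th/95th percentiles,
#' maximum, sample standard deviation (n - 1 denominator) and standard error
#' (sd / sqrt(n)).  Percentiles use linear interpolation between order
#' statistics ([stats::quantile()] type 7).
#'
#' @param x Numeric vector.
#' @return Named numeric vector of the ten statistics.
#' @export
summary_stats <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.10, 0.50, 0.90, 0.95), names = FALSE,
                       type = 7)
  s <- stats::sd(x)
  c(minimum = min(x), p5 = q[1], p10 = q[2], median = q[3], mean = mean(x),
    p90 = q[4], p95 = q[5], maximum = max(x),
    sd = s, se = s / sqrt(length(x)))
}

#' Sensitivity of modelled concentrations to the export-coefficient range
#'
#' Runs the full model three times, with the minimum, median and maximum
#' export-coefficient columns, and summarises the lowest, mean and highest
#' in-lake concentration under each setting together with each setting's
#' ratio to the median-coefficient (default) run, in percent.
#'
#' @param network A [catchment_network()].
#' @param ec An [ec_table()] carrying min/median/max columns.
#' @param ... Further arguments passed to [route_network()].
#' @return A list of class `"ec_sensitivity"`: `concentrations` (matrix,
#'   lakes x settings), `summary` (rows lowest/mean/highest, columns the
#'   three settings) and `ratio_pct` (same rows, min and max settings as a
#'   percentage of the median run).
#' @export
ec_sensitivity <- function(network, ec = default_export_coefficients(), ...) {
  settings <- c("min", "median", "max")
  conc <- lapply(settings, function(s) {
    routed_concentrations(route_network(network, ec = ec, setting = s, ...))
  })
  names(conc) <- settings
  if (!length(conc$median)) {
    phos_error("network contains no standing waters", "domain_error")
  }
  mat <- do.call(cbind, conc)
  summary <- rbind(lowest = apply(mat, 2, min),
                   mean = apply(mat, 2, mean),
                   highest = apply(mat, 2, max))
  ratio <- 100 * summary[, c("min", "max")] / summary[, "median"]
  structure(list(concentrations = mat, summary = summary, ratio_pct = ratio),
            class = "ec_sensitivity")
}

#' Sensitivity of modelled concentrations to discharge
#'
#' Re-runs the full model with every local discharge scaled by each
#' multiplier (default plus and minus 10% in steps of 5%) and reports the
#' [summary_stats()] of the in-lake concentrations per multiplier, with the
#' unscaled baseline included as multiplier 1.
#'
#' @param network A [catchment_network()].
#' @param multipliers Positive discharge multipliers.
#' @param ... Further arguments passed to [route_network()].
#' @return A list of class `"discharge_sensitivity"`: `concentrations`
#'   (lakes x multipliers) and `summary` (statistics x multipliers).
#' @export
discharge_sensitivity <- function(network,
                                  multipliers = c(0.90, 0.95, 1.05, 1.10),
                                  ...) {
  if (any(multipliers <= 0)) {
    phos_error("discharge multipliers must be positive", "domain_error")
  }
  mult <- sort(unique(c(1, multipliers)))
  runs <- lapply(mult, function(m) {
    routed_concentrations(route_network(network, discharge_multiplier = m,
                                        ...))
  })
  if (!length(runs[[1]])) {
    phos_error("network contains no standing waters", "domain_error")
  }
  conc <- do.call(cbind, runs)
  colnames(conc) <- sprintf("x%.2f", mult)
  summary <- apply(conc, 2, summary_stats)
  structure(list(multipliers = mult, concentrations = conc,
                 summary = summary),
            class = "discharge_sensitivity")
}

# Mean lake concentration under a perturbed configuration.
oat_mean_conc <- function(network, param, value, base) {
  args <- list(network = network, ec = base$ec, rates = base$rates,
               oecd = base$oecd, setting = base$setting,
               discharge_multiplier = base$discharge_multiplier)
  switch(param,
    ec_setting = args$setting <- value,
    urban_per_capita = args$rates <- per_capita_rates(value,
                                                      base$rates$septic),
    septic_per_capita = args$rates <- per_capita_rates(base$rates$urban,
                                                       value),
    discharge_multiplier = args$discharge_multiplier <- value,
    depth_threshold = args$oecd <- oecd_parameters(
      base$oecd$shallow[["a"]], base$oecd$shallow[["b"]],
      base$oecd$combined[["a"]], base$oecd$combined[["b"]], value),
    phos_error(sprintf("unknown sensitivity parameter %s", sQuote(param)),
               "domain_error"))
  mean(routed_concentrations(do.call(route_network, args)))
}

#' One-at-a-time parameter sensitivity
#'
#' Perturbs one named parameter at a time over its grid while holding all
#' others at their defaults, and ranks parameters by the largest absolute
#' relative change in the mean in-lake concentration.
#'
#' Recognised parameter names: `ec_setting` (values among "min", "median",
#' "max"), `urban_per_capita`, `septic_per_capita` (kg P/person/yr),
#' `discharge_multiplier`, `depth_threshold` (m).
#'
#' @param network A [catchment_network()].
#' @param grid Named list mapping parameter names to vectors of trial values.
#' @param ec,rates,oecd,setting,discharge_multiplier Baseline configuration.
#' @return A data.frame with columns `parameter`, `max_abs_rel_change` and
#'   `worst_value`, ranked by decreasing effect; empty for an empty grid.
#' @export
one_at_a_time <- function(network, grid,
                          ec = default_export_coefficients(),
                          rates = per_capita_rates(),
                          oecd = oecd_parameters(),
                          setting = "median", discharge_multiplier = 1) {
  base <- list(ec = ec, rates = rates, oecd = oecd, setting = setting,
               discharge_multiplier = discharge_multiplier)
  empty <- data.frame(parameter = character(),
                      max_abs_rel_change = numeric(),
                      worst_value = character(), stringsAsFactors = FALSE)
  if (!length(grid)) return(empty)
  if (is.null(names(grid)) || any(!nzchar(names(grid)))) {
    phos_error("sensitivity grid must be a named list", "domain_error")
  }
  baseline <- mean(routed_concentrations(do.call(
    route_network, c(list(network = network), base[c("ec", "rates", "oecd",
                                                     "setting",
                                                     "discharge_multiplier")]))))
  rows <- lapply(names(grid), function(param) {
    vals <- grid[[param]]
    if (!length(vals)) {
      return(data.frame(parameter = param, max_abs_rel_change = 0,
                        worst_value = NA_character_))
    }
    eff <- vapply(vals, function(v) {
      abs(oat_mean_conc(network, param, v, base) - baseline) / baseline
    }, 0)
    data.frame(parameter = param, max_abs_rel_change = max(eff),
               worst_value = as.character(vals[which.max(eff)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$max_abs_rel_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}
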