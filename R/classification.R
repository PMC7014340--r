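#' WFD status classes
#'
#' @return Character vector of the five Water Framework Directive status
#'   classes, best to worst; ordinal ranks run 0 (High) to 4 (Bad).
#' @export
wfdClasses <- function() c("High", "Good", "Moderate", "Poor", "Bad")

#' Ordinal rank of WFD classes
#'
#' @param class Character vector of class names.
#' @return Integer ranks, 0 (High) to 4 (Bad).
#' @export
wfd_rank <- function(class) {
  r <- match(class, wfdClasses()) - 1L
  if (anyNA(r)) phos_error("unknown WFD class", "domain_error")
  r
}

# Accepts a breakpoint row (data.frame) or named/plain numeric of length 4.
as_breakpoint_vector <- function(bp) {
  if (is.data.frame(bp)) {
    stopifnot(nrow(bp) == 1)
    bp <- c(hg = bp$hg, gm = bp$gm, mp = bp$mp, pb = bp$pb)
  }
  if (!is.numeric(bp) || length(bp) != 4) {
    phos_error("breakpoints must be four concentrations (hg, gm, mp, pb)",
               "config_error")
  }
  bp <- unname(bp)
  if (any(bp <= 0) || any(diff(bp) <= 0)) {
    phos_error("breakpoints must be positive and strictly increasing",
               "config_error")
  }
  stats::setNames(bp, c("hg", "gm", "mp", "pb"))
}

#' WFD status from a TP concentration
#'
#' Boundaries are inclusive upward: a concentration exactly at a class
#' boundary keeps the better class.
#'
#' @param conc_ugl TP concentration(s), ug P/l, >= 0.
#' @param breakpoints Class-boundary concentrations: a named numeric
#'   `c(hg=, gm=, mp=, pb=)`, a plain increasing numeric of length 4, or a
#'   single breakpoint table row.
#' @return Character vector of classes.
#' @export
wfd_status <- function(conc_ugl, breakpoints) {
  if (any(conc_ugl < 0)) {
    phos_error("concentration must be non-negative", "domain_error")
  }
  bp <- as_breakpoint_vector(breakpoints)
  cls <- wfdClasses()[1 + findInterval(conc_ugl, bp, left.open = TRUE)]
  cls
}

#' Trophic state from a TP concentration
#'
#' Below 10 ug P/l oligotrophic, 10 to 20 inclusive mesotrophic, above 20
#' eutrophic.
#'
#' @param conc_ugl TP concentration(s), ug P/l, >= 0.
#' @return Character vector: "oligotrophic", "mesotrophic" or "eutrophic".
#' @export
trophic_class <- function(conc_ugl) {
  if (any(conc_ugl < 0)) {
    phos_error("concentration must be non-negative", "domain_error")
  }
  ifelse(conc_ugl < 10, "oligotrophic",
         ifelse(conc_ugl <= 20, "mesotrophic", "eutrophic"))
}

#' Red-amber-green proximity to a class boundary
#'
#' Flags how close a modelled concentration sits to a target class boundary:
#' red above the boundary, amber within the fraction `amber_fraction` below
#' it (boundary value itself is amber), green otherwise.
#'
#' @param conc_ugl TP concentration(s), ug P/l, >= 0.
#' @param breakpoints As in [wfd_status()].
#' @param target_boundary Which boundary to assess against: `"hg"`, `"gm"`
#'   (default, the good/moderate boundary relevant to GES), `"mp"` or `"pb"`.
#' @param amber_fraction Width of the amber band as a fraction of the
#'   boundary, in (0, 1); default 0.10.
#' @return Character vector: "green", "amber" or "red".
#' @export
traffic_light <- function(conc_ugl, breakpoints, target_boundary = "gm",
                          amber_fraction = 0.10) {
  if (!is.numeric(amber_fraction) || amber_fraction <= 0 ||
      amber_fraction >= 1) {
    phos_error("amber_fraction must lie in (0, 1)", "domain_error")
  }
  if (any(conc_ugl < 0)) {
    phos_error("concentration must be non-negative", "domain_error")
  }
  bp <- as_breakpoint_vector(breakpoints)
  if (!target_boundary %in% names(bp)) {
    phos_error("target_boundary must be one of hg, gm, mp, pb", "domain_error")
  }
  b <- bp[[target_boundary]]
  ifelse(conc_ugl > b, "red",
         ifelse(conc_ugl > (1 - amber_fraction) * b, "amber", "green"))
}

#' Headroom: additional load a waterbody can absorb before downgrading
#'
#' Computes the current in-lake concentration and class, inverts the OECD
#' model at the boundary of that class (the concentration whose crossing
#' would downgrade the status), and returns the load difference.  A
#' waterbody already in the Bad class has no further boundary; it is
#' reported with zero headroom and `boundary_exceeded = TRUE`.
#'
#' @param current_load_kg_yr Current annual load delivered to the lake.
#' @param discharge_m3_yr Annual outflow, m^3/yr (> 0).
#' @param lake A [water_body()].
#' @param breakpoints As in [wfd_status()].
#' @param params An [oecd_parameters()].
#' @return List with `headroom_kg_yr` (>= 0), `boundary_exceeded`, `class`,
#'   `conc_ugl` and `boundary_ugl` (`NA` for the Bad class).
#' @export
headroom_load <- function(current_load_kg_yr, discharge_m3_yr, lake,
                          breakpoints, params = oecd_parameters()) {
  bp <- as_breakpoint_vector(breakpoints)
  pred <- lake_concentration(current_load_kg_yr, discharge_m3_yr, lake, params)
  cls <- wfd_status(pred$tp_lake, bp)
  if (cls == "Bad") {
    return(list(headroom_kg_yr = 0, boundary_exceeded = TRUE, class = cls,
                conc_ugl = pred$tp_lake, boundary_ugl = NA_real_))
  }
  boundary <- bp[[c(High = "hg", Good = "gm", Moderate = "mp",
                    Poor = "pb")[[cls]]]]
  at_boundary <- load_for_concentration(boundary, discharge_m3_yr, lake,
                                        params)
  head <- at_boundary - current_load_kg_yr
  list(headroom_kg_yr = max(0, head), boundary_exceeded = head < 0,
       class = cls, conc_ugl = pred$tp_lake, boundary_ugl = boundary)
}

#' Modelled-versus-measured class comparison matrix
#'
#' Cross-tabulates paired modelled and measured WFD classes and summarises
#' agreement: the percentage of exact matches and the cumulative percentage
#' of pairs whose class ranks differ by at most k, for k = 0..4.
#'
#' @param modelled,measured Character vectors of WFD classes, equal length.
#' @return A list of class `"class_comparison"`: `counts` (5x5 matrix,
#'   measured in rows, modelled in columns), `n`, `exact_pct`, and
#'   `within_pct` (named cumulative percentages for rank differences 0 to 4).
#' @export
comparison_matrix <- function(modelled, measured) {
  if (length(modelled) != length(measured)) {
    phos_error("modelled and measured class lists differ in length",
               "domain_error")
  }
  mo <- factor(modelled, levels = wfdClasses())
  me <- factor(measured, levels = wfdClasses())
  if (anyNA(mo) || anyNA(me)) phos_error("unknown WFD class", "domain_error")
  counts <- table(measured = me, modelled = mo)
  n <- length(modelled)
  dif <- abs(wfd_rank(modelled) - wfd_rank(measured))
  within <- vapply(0:4, function(k) 100 * mean(dif <= k), 0)
  structure(list(counts = unclass(counts), n = n,
                 exact_pct = within[[1]],
                 within_pct = stats::setNames(within, paste0("k", 0:4))),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("class comparison over %d waterbodies\n", x$n))
  print(x$counts)
  cat(sprintf("exact agreement %.1f%%; within one class %.1f%%\n",
              x$exact_pct, x$within_pct[["k1"]]))
  invisible(x)
}
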