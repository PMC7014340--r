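#' Annual runoff from an annual water balance
#'
#' Actual evapotranspiration is taken as the smaller of precipitation and
#' potential evapotranspiration; runoff is the non-negative remainder,
#' `max(0, precip - min(precip, pet))` mm/yr.
#'
#' @param precip_mm,pet_mm Annual precipitation and potential
#'   evapotranspiration, mm/yr, both >= 0.
#' @return Runoff in mm/yr.
#' @examples
#' annual_runoff(2000, 450)  # 1550
#' @export
annual_runoff <- function(precip_mm, pet_mm) {
  if (any(precip_mm < 0) || any(pet_mm < 0)) {
    phos_error("precipitation and PET must be non-negative", "domain_error")
  }
  aet <- pmin(precip_mm, pet_mm)
  pmax(0, precip_mm - aet)
}

#' Annual discharge volume from runoff depth and catchment area
#'
#' `runoff_mm / 1000 * area_ha * 1e4` cubic metres per year: one metre of
#' runoff over one square kilometre is a million cubic metres.
#'
#' @param runoff_mm Annual runoff, mm/yr.
#' @param area_ha Contributing area, ha.
#' @return Discharge in m^3/yr.
#' @export
annual_discharge <- function(runoff_mm, area_ha) {
  if (any(runoff_mm < 0) || any(area_ha < 0)) {
    phos_error("runoff and area must be non-negative", "domain_error")
  }
  runoff_mm / 1000 * area_ha * 1e4
}

#' Lake residence time
#'
#' Volume divided by annual outflow, in years.  Zero outflow returns `Inf`
#' as the distinguished no-flushing value.
#'
#' @param volume_m3 Lake volume, m^3 (> 0).
#' @param outflow_m3_yr Annual outflow, m^3/yr (>= 0).
#' @return Residence time in years (possibly `Inf`).
#' @export
residence_time <- function(volume_m3, outflow_m3_yr) {
  if (any(volume_m3 <= 0)) {
    phos_error("lake volume must be positive", "domain_error")
  }
  if (any(outflow_m3_yr < 0)) {
    phos_error("outflow must be non-negative", "domain_error")
  }
  ifelse(outflow_m3_yr == 0, Inf, volume_m3 / outflow_m3_yr)
}
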