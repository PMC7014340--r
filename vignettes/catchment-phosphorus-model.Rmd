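---
title: "Modelling catchment phosphorus export and lake status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling catchment phosphorus export and lake status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscade)
```

## The problem

Most standing waters in a national monitoring programme are never sampled:
regulators need a defensible estimate of total phosphorus (TP) concentration
— and hence Water Framework Directive (WFD) status — for thousands of
unmonitored lakes and reservoirs. Export-coefficient models fill this gap.
They trade process detail for data availability: every phosphorus source in
a catchment is assigned an annual export rate, the rates are summed into a
load, and an empirical retention model converts the load into an in-lake
concentration.

`phoscade` implements that chain for networks of sub-catchments: diffuse
land-cover export, per-capita waste-water and septic-tank loads, additive
point sources, an annual water balance, cascading routing down the drainage
network, the OECD/Vollenweider load-to-concentration model, and
classification against per-waterbody WFD breakpoints.

## Source terms

**Land cover.** Each parcel contributes `area_ha × EC(category, slope)`
kg P/yr. The packaged coefficient table covers 18 land-cover categories in
three slope bands (Low 0–4°, Medium 4–13°, High 13°+; bands are
lower-inclusive, so 4° is Medium and 13° is High — the published band labels
repeat the boundary values, so a convention had to be fixed). Coefficients
rise with slope and are highest for arable, disturbed-forestry and urban
surfaces; Water, Wetland and Cliffs carry a single slope-invariant value,
and estuarine/sealed categories are retained with a zero coefficient so
that area accounting stays complete.

Each (category, slope) cell carries a minimum, median and maximum rate. The
medians are the model defaults. Only two extreme ranges of the original
calibration are documented (wetlands 0.02–0.15 kg/ha/yr; grasslands on
steep slopes 0.08–0.15); the remaining ranges in the packaged table are
synthetic defaults — median ÷ 1.5 and median × 1.5 — flagged as such in
`?default_export_coefficients`, so that the sensitivity mode runs out of
the box. Users with a calibrated range table can supply their own CSV.

**Population.** Urban population is assumed to discharge through
waste-water treatment works at 0.9125 kg P/person/yr; rural population on
septic tanks contributes 0.25 kg P/person/yr, counting only tanks in the
riparian zone. Treatment-works locations are not modelled: the load is
attributed to the sub-catchment of residence. Where actual works data
exist, a `wwtw_override` extra source *replaces* the per-capita urban term
(this also covers works that export effluent out of the catchment, where
the override is zero).

**Extra sources.** Fish farms, cage aquaculture, roosting birds,
atmospheric deposition and other sources enter as plain additive annual
loads.

## Hydrology and the lake model

The annual water balance is deliberately minimal: actual evapotranspiration
is capped at precipitation, runoff is `max(0, precip − pet)` mm/yr, and
discharge is runoff times catchment area. Potential evapotranspiration is a
required input, not computed here, and an optional per-catchment
`runoff_coeff` multiplier lets users emulate soil-hydrology effects. Lakes
pass all water through: residence time is `volume / outflow`, with zero
outflow treated as a no-flushing error rather than approximated, and
zero-volume lakes disallowed.

The in-lake concentration follows the OECD empirical form

$$TP_{lake} = a \left( \frac{TP_{in}}{1 + \sqrt{\tau}} \right)^{b}$$

with `TP_in = load / discharge × 10⁶` µg P/l and τ in years. Two fitted
pairs are carried: shallow lakes and reservoirs (a = 1.02, b = 0.88) and
the combined data set (a = 1.55, b = 0.82), selected by a mean-depth
threshold of 3.0 m (the boundary itself is assigned to the shallow pair;
only "a threshold of 3.0 m" is documented, so the tie had to be broken).
Some sources call `a` a "denominator"; it is implemented as a multiplier,
which the cross-parameter consistency check fixes unambiguously: inverting
the combined curve at 53.8 µg/l and re-evaluating the shallow curve at the
same inflow term yields 45.9 µg/l, matching the documented Loch Leven pair.

At very small inflow concentrations the fitted curve with a > 1 can predict
`TP_lake > TP_in` (apparent negative retention). Predictions are not
clipped; the retention fraction is reported as a diagnostic.

The model inverts exactly (`load_for_concentration`), which powers headroom
estimates, and at fixed hydrology implies `C ∝ L^b`, the scaling shortcut
exposed as `scale_concentration` / `scale_load`.

## Routing

Sub-catchments form a forest of directed trees (out-degree ≤ 1, validated
with a cycle diagnosis naming an offending edge). Loads and discharge
accumulate in topological order. The default retention mode applies the
OECD model at *every* lake, so upstream lakes trap phosphorus before
passing the remainder on — consistent with a model that accounts for flows
and residence times within the catchment. Because the original
upstream-retention rule is not documented, `terminal_only` is offered as
the alternative: upstream lakes still receive concentration predictions but
their inflow passes through unretained, which makes outlet load exactly the
sum of local loads (the mass-balance property the tests check). No
in-stream attenuation is applied between catchments. Upstream load is
apportioned as a single `upstream` component rather than re-split by
original source.

## Classification

Status boundaries are inclusive upward: a concentration exactly at a
boundary keeps the better class. Trophic thresholds are <10 µg P/l
oligotrophic, 10–20 inclusive mesotrophic, >20 eutrophic. The traffic light
is defined on concentration: red above the target boundary (good/moderate
by default), amber within 10% below it (the 10% amber band is a
configurable package default; the width of the original indicator is not
documented), green otherwise. Headroom inverts the lake model at the
current class boundary; waterbodies already in Bad have no further boundary
and are flagged instead.

## Scenarios and sensitivity

Scenario records (land-cover transfer, extra-source add/remove,
precipitation/PET scaling, population and per-capita changes) produce a
modified copy of the network; the baseline object is never touched, so
baseline runs are bit-reproducible after any number of scenario runs.
Climate enters scenarios only through the water balance — no other climate
pathway is modelled.

The sensitivity drivers reproduce two standard procedures: a three-way run
over the minimum/median/maximum coefficient columns, summarised as lowest,
mean and highest concentration per setting with ratios to the median run;
and discharge perturbation at ±10% in 5% steps, summarised by minimum, 5th
and 10th percentiles, median, mean, 90th and 95th percentiles, maximum,
standard deviation (n − 1) and standard error. Percentiles use linear
interpolation between order statistics (`quantile` type 7); the original
report does not state its estimator, so this common default was fixed once.
`one_at_a_time` perturbs one named parameter over a grid while holding the
rest constant and ranks parameters by the largest absolute relative change
in mean concentration.

## Synthetic networks and case-study fixtures

`generate_network` builds seeded random drainage trees under four landscape
profiles. Upland profiles draw heather/peat/montane covers, steep slopes,
sparse populations and ~2000 mm rainfall; lowland profiles draw
arable/improved-grassland covers, gentle slopes and drier climate; urban
profiles add sealed surfaces and log-normal populations in the thousands;
mixed blends them. Lake depths are drawn across 1–8 m so both OECD presets
are exercised. The generator emulates the *structure* of real attribute
tables — it makes no claim to spatial realism, and passing tests on
synthetic networks demonstrate internal consistency (mass balance,
monotonicity, determinism), not predictive skill on real catchments.

Six calibrated single-lake fixtures (`case_study`) encode well-documented
worked examples spanning the model's failure modes: missing bird/aerosol
sources (Heldale), a works that exports its effluent (Skene, corrected with
a zero `wwtw_override` plus a 450 kg/yr goose load), parameter-set choice
at the depth threshold (Leven), historical aquaculture/bird/rain loads
(Menteith), dominant urban waste water (Strathclyde, 91.5% of the budget),
and an unexplained load that even an all-arable scenario cannot close
(Milton). The published record prints loads, concentrations and statuses
but not hydrology, so each fixture back-solves a discharge/residence-time
pair consistent with its printed (load, concentration) under the
depth-appropriate preset (a one-dimensional root find; the concentration is
strictly decreasing in outflow, so the solution is unique). Lake
morphometry, climate, land-cover composition and breakpoint values are
synthetic choices made once, constrained to agree with every printed value
(land-cover contribution, urban share, class assignments of the measured
and modelled concentrations); they are recorded in the returned network
object and documented in `?case_study`.

## Numerical choices and problem sizes

- Concentration/load unit conversion is fixed at 1 kg / 10³ m³ = 1000 µg/l.
- Fixture calibration root-finding runs on log₁₀ discharge over
  [1, 10¹⁵] m³/yr at tolerance 10⁻¹³, giving forward runs that reproduce
  the calibrated concentrations to machine precision.
- The inversion round trip `load_for_concentration(lake_concentration(L))`
  is exact to 10⁻¹⁰ relative and tested as such.
- Parcel tables may carry slope in degrees or as a class; degrees win when
  both are present. Parcels summing to less than the catchment area are
  allowed — the unmapped remainder contributes zero load but full runoff.
- Test and validation problem sizes: property suites run on seeded random
  networks of 2–20 nodes (200 networks for the routing oracle, which
  re-derives every node's load by brute-force path enumeration), and
  generator checks use 5–20 node networks; these sizes fully exercise the
  branching logic while keeping the default suite fast.

## Known limitations

Livestock are folded into the improved-grassland coefficient rather than
modelled by headcount; phosphorus stripping at treatment works is not
represented; septic loads are not attenuated with distance; internal
sediment phosphorus loading is outside the model (the Milton fixture is
precisely a case where it likely matters); and the water balance is annual,
with no snow, groundwater or monthly dynamics.
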