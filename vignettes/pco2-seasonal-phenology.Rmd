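---
title: "Methods: seasonal phenology of surface-ocean pCO2 under rising CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal phenology of surface-ocean pCO2 under rising CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the numerical choices behind
`pco2phen`: what each stage of the pipeline computes, which assumptions it
makes, which parameters matter, and what the synthetic-data generator does
and does not emulate.

## 1. Carbonate-system solver

The solver finds the total-scale hydrogen-ion concentration \[H⁺\] at which
the total-alkalinity balance closes, given temperature `T` (°C), practical
salinity `S`, total alkalinity `A_T` and total dissolved inorganic carbon
`C_T` (both µmol kg⁻¹), plus optional phosphate and silicate totals. The
alkalinity expression includes carbonate, borate, water, free-hydrogen,
phosphate and silicate terms. Ammonia, sulfide and the bisulfate/fluoride
alkalinity contributions are omitted — negligible at open-ocean
concentrations — although total sulfate and fluoride are carried for the pH
scale conversions.

**Constants.** One named registry, `"lueker2000_total"`: Lueker et
al. (2000) carbonic-acid constants on the total pH scale, Weiss (1974) CO₂
solubility and fugacity virial coefficients, Dickson (1990) borate and
bisulfate, Millero (1995) water/phosphoric/silicic acid (converted from the
seawater to the total scale), Lee et al. (2010) total boron, Perez & Fraga
(1987) fluoride (scale conversion only). The registry name is recorded in
the provenance block of every pipeline report so alternative formulations
can be added and traced.

**Root finding.** Safeguarded Newton iteration on \[H⁺\] (numerical
derivative at a relative step of 10⁻⁷), initial guess pH 8.0, maintained
inside a bisection bracket over pH ∈ [1, 13]; any Newton step leaving the
bracket is replaced by the geometric midpoint. Convergence is declared when
the relative \[H⁺\] step falls below 10⁻¹² (100-iteration cap, after which
the offending states are reported and the call fails). Because the residual
is strictly decreasing in \[H⁺\], a sign change over the bracket guarantees
a unique root; states with no sign change (no physical root) fail
explicitly, naming the alkalinity/DIC pair. The solver is fully vectorized
over states, which is what makes per-cell, per-month chemistry across a
century of monthly fields affordable.

Two identities hold *by construction* and are asserted in the tests rather
than tuned: carbon conservation (`co2star + hco3 + co3 = dic`) and the
Henry/K1 identity `pCO2 = [H⁺][HCO₃⁻]/(C_f K₀ K₁)`. The fugacity
coefficient `C_f` is evaluated at 1 atm total pressure; the package is
surface-only and has no pressure dependence.

**Sensitivities.** ∂pCO₂/∂X is computed by central differences with
absolute steps 10⁻³ °C, 10⁻³ (salinity) and 0.1 µmol kg⁻¹ (A_T, C_T) —
about 10⁻⁴ of each driver's characteristic seasonal range. If a perturbed
state leaves the valid range the step is halved once, then the call fails.
Step-halving changes the results by less than 10⁻⁴ relative (checked in the
tests), so truncation error is far below every downstream tolerance.

**The pCO₂ vs \[CO₂*\] temperature-sensitivity ratio.** For a closed system
(fixed A_T, C_T), d ln pCO₂/dT − d ln [CO₂*]/dT = −d ln(K₀C_f)/dT exactly,
so pCO₂ reacts much faster to warming than aqueous CO₂ wherever solubility
falls steeply with temperature. The often-quoted factor of about seven comes without an authoritative
temperature/salinity, so the package maps the ratio rather than assuming it: at A_T = 2130, C_T = 2000 µmol kg⁻¹ the
ratio is ≈ 7 for T between roughly −1.5 and +0.5 °C (S 30–35) — the modern
polar surface band — declining to ≈ 3 at 25 °C. The package's default
evaluation state is T = −1 °C, S = 33, chosen as representative of the
modern Arctic surface before the acceptance assertions were written.

## 2. Detrending and climatologies

Monthly anomalies "relative to the annual mean" are computed by subtracting
a cubic smoothing spline fit through the series of annual means. Design
choices, made once and kept:

* The spline is fit to *annual means* (not all monthly points), at knots
  placed at each year's mean month midpoint on a 365-day no-leap calendar
  (≈ year + 0.498 — not 0.5, because months differ in length; using 0.5
  leaves a small constant offset and breaks idempotence). It is evaluated
  at month midpoints and subtracted.
* The smoothing parameter `spar` is exposed; the default (`NULL`) uses
  generalized cross-validation. Because the penalty null space is linear
  functions, any linear secular trend is removed exactly at every `spar`.
* First and last years are flagged `edge_year` (spline boundary, natural
  conditions, lower confidence).
* Degenerate input (a constant series) short-circuits to a flat trend.

Consequences checked as properties: detrending is idempotent to 10⁻⁶ of the
anomaly amplitude, linear in the data, and exact on cycle-plus-linear-trend
constructions away from edge years. Decadal climatologies are month-wise
means of these anomalies over a fully covered year range (partial coverage
fails), re-centred to zero mean, with the annual mean of the undetrended
series stored alongside.

Two summer-month presets are provided for the summer-anomaly statistic:
`"jas_skip_jul"` (June, August, September — the default, matching one
convention seen in summer-anomaly maps) and `"jja"` (June–August, the
conventional reading). Neither is silently preferred; the window is always an explicit
argument. Stage classification, crossover detection and enhancement
statistics use the wider June–September window by default, which brackets
both presets.

## 3. Taylor decompositions

**Basic approach.** Each driver term is `γ_i[m] · X′_i[m]` where the
effective sensitivity `γ_i[m]` is the arithmetic mean of the monthly
sensitivity (evaluated at the decadal monthly climatological state) and the
annual-mean sensitivity. "Annual-mean sensitivity" is implemented as the
mean of the twelve monthly sensitivities (not the sensitivity at the
annual-mean state); the two readings differ at second order and the chosen
one keeps the averaging linear in the sensitivities. This averaging is
quietly powerful: it makes the reconstruction accurate to *third* order in
the anomalies, because `(γ(X̄+X′) + γ(X̄))/2 ≈ γ(X̄) + ½∇γ·X′` reproduces
the full second-order Taylor term, cross-couplings included. Phosphate and
silicate are included in the carbonate solves but excluded from the terms,
so the reported closure error honestly reflects their neglect together with
all higher-order terms. Closure (max |Σ terms − actual p′CO₂| relative to
the anomaly amplitude) is attached to every term series and never hidden.

**Freshwater-separated layout.** The A_T and C_T terms are split into a
salinity-driven (freshwater) part and a biogeochemical part driven by the
salinity-normalized quantities `sX = X·S₀/S`, with S₀ the annual-mean
salinity of the cell. The biogeochemical terms retain the S/S₀ prefactor,
which matters where short-term salinity variability is large (melt-season
freshening). The printed first-order dilution form `(X/S)·γ_X·S′` does not
sum *exactly* to the standard layout (the split is a linearization), so this
package computes the freshwater terms as the exact complement
`γ_X·(X′ − (S/S₀)·sX′)` — equal to the dilution form to first order — making
the two layouts' totals identical to machine precision. The tests verify
both the limiting regimes (constant salinity: freshwater terms vanish; pure
proportional dilution: biogeochemical terms vanish) and the equality of
totals.

**Incremental (year-pair) decomposition.** A single linearization step
across eight decades degrades when driver anomalies and sensitivities both
change strongly. The incremental procedure instead accumulates many small
first-order steps: for each month, the driver change between consecutive
years is multiplied by the pair-averaged monthly sensitivity; the products
are summed across years into a per-term decomposition of the
modern-to-future change; and that change is added to the modern terms, each
term being re-centred over the twelve months at the end. Two numerical
choices matter:

* *Year-pair weights.* Pairs are weighted by the number of lagged
  ten-year windows they connect (0.1, 0.2, …, 1, …, 0.2, 0.1 across the
  decade edges), so that with constant sensitivities the telescoped sum
  reproduces the difference of the two decadal climatologies exactly — and
  hence the basic decomposition of the future decade, a property the tests
  assert.
* *Trend handling.* Each year-pair driver change is taken as the change of
  the detrended monthly anomaly plus the month-independent step of the
  annual-mean trend. Keeping the trend step lets the accumulated products
  track the system's path through states of growing sensitivity (dropping
  it loses the ∫X′dγ part of the change and badly underestimates the future
  terms); using the anomaly change rather than the raw monthly difference
  keeps the detrending spline's within-year ramp — an interpolation
  artifact with the same sign in every month — out of the seasonal
  decomposition.

In the regime the generator's defaults produce, the basic approach is
already accurate (third-order, smooth moderate anomalies) and the
incremental route has no advantage; its value appears under strong forcing.
The stress configuration used in the acceptance suite
(`summer_warming_gain = 4.5` °C month⁻¹, `bio_drawdown = 70` µmol kg⁻¹,
`warming_per_doubling = 4` °C, pathway to 1400 ppm, noise off) produces
end-of-century anomalies large enough that the basic closure degrades while
the incremental closure does not; the acceptance script reports both.

**Thermal/non-thermal split.** `thermal` is the temperature term;
`nonthermal` is defined two ways, both exposed: the sum of the non-thermal
Taylor terms (`reconstructed_total − thermal`) and the residual from the
actual anomalies (`actual_total − thermal`). Their difference is exactly the
closure error, so neither hides it.

## 4. Climate–CO₂ separation

The modern→future change in p′CO₂ is written as ΣΔγ·X′₀ (changed
sensitivities — the geochemical effect of higher CO₂) + Σγ₀·ΔX′ (changed
driver anomalies — the radiative effect of physical climate change) +
ΣΔγ·ΔX′ (synergy). The identity `total = delta_sens + delta_anom + synergy`
is exact arithmetic, asserted as `expect_identical` over a thousand random
draws. `delta_anom_star = delta_anom + synergy` folds the synergy into the
driver-anomaly effect (the future state minus the state computed with only
increased sensitivities). The separation uses the same effective
sensitivities as the basic Taylor decomposition, so the separation total
equals the difference of the two decades' reconstructions.

Summer-enhancement statistics compare the future summer extreme (maximum
monthly anomaly in the summer window) with the extreme of the
sensitivities-only state. Percent variants relative to the modern extreme's
absolute and signed value are both emitted and labelled — the published
percent convention is ambiguous — together with the absolute µatm
difference, which is the stable choice when the modern summer extreme is
near zero (as it is in this emulator, where the modern summer window
straddles the sign change). A seasonal-mean variant accompanies the
extreme-based one. Multi-member statistics are reported as mean ± 1 s.d.
across the ensemble. Multimodel percentages quoted from CMIP-based analyses are archive-specific
and are not reference values for this package; on synthetic input only the
schema and identities are guaranteed.

## 5. Timing and crossover

* **Extreme months** are selected from the twelve area-weighted basin-mean
  values of the decadal climatology; ties break to the earliest month, and
  an all-equal cycle is reported as degenerate rather than assigned a month.
* **Stages.** 1: no maximum in the summer window; 2: a positive local
  maximum (on the circular month topology) in the window while the annual
  maximum lies elsewhere; 3: annual maximum in the window.
* **Crossover** is operationalized as the stage-2→3 transition of the
  smoothed basin series: each month's anomaly is smoothed across CO₂ levels
  with a cubic smoothing spline, the margin (summer maximum minus
  outside-summer maximum) is formed per level, and the crossover CO₂ value
  is linearly interpolated at the margin's first zero crossing. Where both
  definitions apply this coincides with the timing curves of the annual
  high and low crossing, and it stays robust when the low becomes
  indistinct. Detection is invariant to adding a constant to all anomalies
  of a level, and returns "none" when the margin never turns positive (a
  stationary pathway, or a parameterization that never reaches stage 3).
* **Timing curves** record the integer months of high and low per CO₂ level
  and smooth them with a cubic spline *after* unwrapping the circular month
  index to a continuous branch (a Dec→Jan drift must not appear as an
  11-month jump). Smoothed values are mapped back to [1, 13).
* **Smoothing parameter.** The across-level splines default to a fixed
  `spar = 0.6` — moderate smoothing whose purpose is to suppress
  interannual variability. Generalized cross-validation is available but
  unstable on short level sequences (a couple dozen decades), where it can
  oscillate between no smoothing and failure.
* **Ice dates.** Retreat is the first month concentration drops below 0.15,
  growth the first later month it recovers to the threshold; cells that
  never cross have no event and are excluded from the area-weighted mean
  month indices (these means follow the cell-index-averaging convention, in
  contrast to the basin-mean-first convention used for pCO₂ timing). A
  retreat month of July or earlier flags the cell as a late-summer
  transition cell (informational).
* **Debiasing** subtracts the per-cell, per-month historical model bias
  relative to an observational climatology from the future climatology,
  then area-averages each cell's annual maximum over the shelf mask
  (depth < 500 m).

## 6. The synthetic-data generator

The generator produces monthly fields (T, S, A_T, C_T, ice concentration,
NPP) per grid cell along an atmospheric CO₂ pathway, with Gaussian noise,
plus a *truth record* computed from the noise-free construction: per-decade
basin anomalies, stages, the constructed crossover level (margin zero
crossing over decade-mean CO₂), an exact one-at-a-time thermal/non-thermal
split of the basin-mean climatological state, and decadal ice dates.
Identical seeds reproduce the fields bit-for-bit.

Mechanisms emulated, with the defaults (chosen once as representative of a
biologically dominated modern polar ocean, before any acceptance outcome
was seen):

* **Warming**: annual-mean surface warming of `warming_per_doubling`
  (2.5 °C) per CO₂ doubling — polar-amplified relative to the global mean.
* **Ice**: winter concentration near 0.97, a latitude-dependent summer
  minimum, and a retreat date that advances by `ice_retreat_sensitivity`
  (0.6 month °C⁻¹) as the cap warms; freeze-up recedes at half that rate.
* **Summer-amplified warming**: open-water summer temperature gains
  `summer_warming_gain` (2 °C) per month of earlier retreat, on top of a
  small direct warming share; surface temperature is an ice-weighted blend
  of near-freezing (−1.75 °C) and the open-water curve, so ice-covered
  cells barely vary.
* **Biology**: NPP is a Gaussian forcing curve peaking in July, advancing
  with earlier retreat (`npp_phase_advance` 0.4 month/month). The DIC
  deficit has an asymmetric shape — sharp drawdown at the bloom, slow
  linear resupply over the following eight months — so DIC (and hence
  p′CO₂) peaks in late winter/spring, as observed. Peak drawdown is
  `bio_drawdown` (35 µmol kg⁻¹) scaled down where ice cover persists; its
  amplitude does not grow with warming.
* **Secular carbon trend**: the DIC baseline is the preindustrial
  equilibrium value plus `ct_trend_coupling` (0.8) of the equilibrium rise
  implied by the pathway — a disequilibrium knob in place of explicit
  air–sea exchange, which is out of scope; the analysis only needs
  realistic driver trajectories.
* **Freshening**: melt season reduces salinity by up to `melt_dilution`
  (1.2) and dilutes alkalinity and the non-biological part of DIC
  proportionally.

Latitude bands differ in baseline ice, temperature, bloom strength and
salinity, and the two southernmost bands are shallow (shelf), so shelf
cells cross to a summer maximum before deep-basin cells. All couplings are
linear with clamps, and the default amplitudes keep the Taylor expansion's
neglected higher-order terms at the percent level.

What the generator does **not** emulate: ocean dynamics and transport,
sea-ice thermodynamics, air–sea flux kinetics and its multi-month
equilibration timescale, spatially correlated variability, regime-dependent
biology, or model-structural diversity of the kind a multi-model archive
contains. Passing the parameter-recovery tests therefore demonstrates that
the analysis chain is correct and robust to uncorrelated noise at realistic
amplitudes — not that it would be unbiased on any particular Earth-system
model's output.

Pathways: `one_percent` is compound 1 %/yr growth from 284 ppm (first
doubling at year 70, quadrupling at year 140); `rcp_like` is a smooth
quartic ramp from 284 ppm to `end_ppm` (936 by default) over the scenario
years, approximating a slow historical rise that accelerates late; `flat`
is constant. The truth crossover is "remarkably consistent" across
pathways of different steepness for a fixed parameterization, which the
tests assert within the coarser pathway's decade sampling.

## 7. Pipeline, problem sizes and determinism

`run_pipeline()` chains: generate (or accept) fields → solve chemistry per
cell/month → detrend → decadal climatologies (modern and future, plus every
full decade for timing) → sensitivities at the decadal monthly states →
standard + freshwater (and optionally incremental) decompositions per cell,
area-weighted to basin series → climate–CO₂ separation and enhancement →
timing curve, crossover, stages, ice dates. Everything is a pure function
of (config, seeds); reports can be serialized as CSV/JSON with a provenance
block naming the constants set and seeds.

Grid resolution is a free choice: the cap grid supports 1° × 1°, and the
package's own analyses use coarser caps (4–8° latitude bands, 15–45°
longitude steps; a few dozen cells) with 251-year scenarios — basin-scale
statistics converge quickly with cell count because the generator's noise
is uncorrelated, and the vectorized solver makes the chemistry linear in
the number of cell-months. The examples, tests and acceptance script state
their grids explicitly.

## 8. Known limitations

* The solver is surface-only (1 atm); no pressure dependence, no saturation
  states, no air–sea flux computation.
* The freshwater layout's dilution terms use the exact-complement
  definition; studies quoting the first-order printed form will differ at
  second order in S′.
* Crossover detection presumes a monotone CO₂ axis and at least three
  levels; the decadal sampling limits its resolution to roughly one decade
  of the pathway.
* The percent enhancement statistics are unstable when the modern summer
  extreme is near zero; use the µatm variants for quantitative work.
* The generator's truth record shares the package's carbonate solver (the
  truth is about the *construction*, not an independent chemistry); the
  solver itself is validated separately against a brute-force bisection
  oracle.
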