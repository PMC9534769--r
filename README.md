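# pco2phen

Seasonal phenology of surface-ocean pCO₂ under rising atmospheric CO₂.

## The problem

In today's polar surface ocean, the partial pressure of CO₂ (pCO₂) is
typically highest in late winter/spring and lowest in summer: biological
carbon drawdown outweighs the warming effect on CO₂ solubility. As
atmospheric CO₂ rises, two things change at once. The *sensitivities* of
pCO₂ to its drivers grow (a geochemical effect of the higher CO₂ background,
which reduces buffering), and the *driver seasonalities* themselves change
(a radiative effect of physical climate change — most importantly, much
stronger summer sea-surface warming as seasonal sea ice retreats earlier).
Eventually the summer anomaly can flip sign and overtake the winter maximum,
abruptly inverting the chronological order of the annual high and low — with
direct consequences for summer ocean acidification.

`pco2phen` packages the complete analysis chain for studying this
transition, for anyone working with gridded monthly ocean carbonate-system
output (Earth-system models, regional models, or observation-based
products):

* **Carbonate chemistry** — a total-pH-scale equilibrium solver
  (safeguarded Newton on \[H⁺\] with a bisection bracket) returning full
  speciation (pCO₂, \[H⁺\], \[CO₂*\], \[HCO₃⁻\], \[CO₃²⁻\]) from
  temperature `T`, salinity `S`, total alkalinity `A_T` and dissolved
  inorganic carbon `C_T`, plus numerical (central-difference) sensitivities
  ∂pCO₂/∂X for each driver.
* **Anomalies** — cubic-smoothing-spline detrending of monthly series and
  decadal climatologies of the monthly anomalies X′ relative to the annual
  mean.
* **Taylor decompositions** of the monthly pCO₂ anomaly,

  p′CO₂ ≈ (∂pCO₂/∂T)·T′ + (∂pCO₂/∂S)·S′ + (∂pCO₂/∂A_T)·A_T′ + (∂pCO₂/∂C_T)·C_T′,

  in three flavours: the standard four-term layout; a freshwater-separated
  layout that splits the A_T and C_T terms into dilution-driven and
  biogeochemical (salinity-normalized, `sX = X·S₀/S`) parts; and an
  incremental year-pair procedure for end-of-century decades where a single
  linearization step degrades.
* **Climate–CO₂ separation** — attribution of the modern→future change in
  p′CO₂ to changed sensitivities (Δγ·X′₀), changed driver anomalies
  (γ₀·ΔX′) and their synergy (Δγ·ΔX′), with summer-enhancement statistics.
* **Phenology** — months of the annual high/low, the three-stage
  classification of the seasonal cycle (1: no summer maximum, 2: positive
  secondary summer maximum, 3: annual maximum in summer), detection of the
  high/low crossover CO₂ level, sea-ice retreat/growth dates (0.15
  concentration threshold), and debiased shelf summer temperature maxima.
* **A seeded synthetic-data generator** that emulates the statistical
  structure this analysis assumes (seasonal ice with warming-driven earlier
  retreat, summer-amplified warming, biologically driven summer C_T
  drawdown, a secular C_T trend, melt freshening) and records the
  constructed truth (crossover level, thermal/non-thermal split, retreat
  dates) so the whole pipeline can be validated by parameter recovery.

Everything is tidyverse-native: functions take data frames in, return
tibbles, and the result objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

Solve the carbonate system at a polar surface state (alkalinity 2130,
DIC 2000 µmol kg⁻¹, T = 2 °C, S = 33):

```r
library(pco2phen)
solve_carbonate(seawater_state(temp = 2, sal = 33, alk = 2130, dic = 2000))
#>    temp   sal   alk   dic  phos   sil    ph             h  pco2 co2star  hco3   co3
#> 1     2    33  2130  2000     0     0  8.08 0.00000000838  336.    19.7 1885.  95.3
```

pH 8.08 and pCO₂ of 336 µatm are typical modern polar surface values. The
closed-system relative temperature sensitivity of pCO₂ is about seven times
that of \[CO₂*\] at modern polar temperatures — the key reason warming
imprints on pCO₂ much more strongly than on aqueous CO₂:

```r
temperature_sensitivity_ratio(seawater_state(-1, 33, 2130, 2000))$ratio
#> [1] 7.082588
```

Run the full pipeline on a synthetic three-member ensemble along a high-end
concentration pathway (284 → 936 ppm over 1850–2100):

```r
cfg <- pipeline_config(
  scenario = scenario_config("rcp_like"),
  grid = polar_cap_grid(dlat = 8, dlon = 45),
  seeds = 1:3, run_incremental = FALSE
)
res <- run_pipeline(cfg)
glance(res)[, c("crossover_ppm_mean", "crossover_ppm_sd",
                "truth_crossover_ppm_mean", "closure_modern_rel_mean")]
#>   crossover_ppm_mean crossover_ppm_sd truth_crossover_ppm_mean closure_modern_rel_mean
#> 1               537.             1.97                     528.                 0.00901

res$members[[1]]$timing$crossover
#>   co2_ppm month
#> 1    536.     9
```

The ensemble detects the winter-to-summer crossover of the annual pCO₂′
maximum at 537 ± 2 ppm — within one decadal sampling step of the
generator's constructed truth (528 ppm) — occurring in September, and the
modern-decade Taylor reconstruction closes to 0.9 % of the anomaly
amplitude. `autoplot()` on the member's `terms_modern`, `separation` or
`timing$curve` objects draws the corresponding diagnostics, and
`plot_cycle_evolution()` shows the full seasonal cycle marching through the
three stages.

See the methods vignette (`vignettes/pco2-seasonal-phenology.Rmd`) for the
model assumptions, parameter meanings and numerical choices.

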