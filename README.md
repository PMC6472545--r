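# ricesys

Farm-level energy, greenhouse-gas and economic accounting for rice
cropping systems, with a synthetic farm-survey generator and
between-system statistical comparison.

## What it does, and for whom

Agronomists and agro-environmental analysts comparing rice cropping
systems — middle-season rice (MR, one crop per year), double-season rice
(DR, early + late crops) and ratoon rice (RR, a main crop plus a second
harvest regrown from stubble) — need farm-level budgets computed
consistently across hundreds of surveyed fields:

* **Energy balance** — fossil-energy input as Σ rateᵢ × energy
  equivalentᵢ over inputs (fertilizers, irrigation, seed, pesticide,
  diesel, machinery, labor) and crop cycles; grain energy output; net
  energy yield `NEY = Eout − Ein` (GJ ha⁻¹ yr⁻¹) and net energy ratio
  `NER = Eout / Ein`.
* **GHG inventory** — embodied emissions of inputs; direct N₂O from the
  nitrogen surplus through `N₂O-N = a·exp(b·Nsur)` with
  `Nsur = Napplied − Nuptake(yield)` plus 20% indirect; paddy CH₄ as
  `1.3 kg ha⁻¹ d⁻¹ × duration × SFwater × SForganic` per cycle. Totals
  expressed as 100-yr global warming potential
  `GWP = CO₂e + 25·CH₄ + 298·N₂O` (kg CO₂e ha⁻¹ yr⁻¹) and GHG intensity
  `GWPi = GWP / yield` (kg CO₂e Mg⁻¹).
* **Economics** — gross income, variable production cost, net return,
  benefit-to-cost ratio, net profit per labor hour (NPL), eco-efficiency
  (net return per Mg CO₂e), and the input-use efficiencies LP, PFP_N and
  IWP.
* **Comparison** — per-system six-statistic summaries (min, P25, mean,
  P75, max, CV), one-way ANOVA with Fisher's LSD letters, and
  within-system/pooled OLS regressions.

Per-item coefficients and prices are calibrated so the packaged defaults
reproduce published system-level benchmarks for central China (2016);
a deterministic generator emulates the 240-field survey (80 fields per
system) those benchmarks summarize. See the methods vignette
(`vignettes/rice-cropping-systems.Rmd`) for the models, calibration and
its limits.

## Worked example

```r
library(ricesys)

survey <- generate_survey(seed = 1)          # 240 fields, 80 per system
ind    <- compute_indicators(survey)         # per-field indicator table
fit_linear(ind$energy_input, ind$energy_output)
#> # A tibble: 1 × 5
#>   slope intercept r_squared slope_p_value     n
#>   <dbl>     <dbl>     <dbl>         <dbl> <int>
#> 1  3.90      26.5     0.803      8.39e-86   240
```

The pooled regression of grain energy output on fossil-energy input
recovers a slope of ~3.9 GJ per GJ: each extra gigajoule of fossil
energy is associated with about four gigajoules of additional grain
energy across the three systems. Per-system means from the same run
(`analysis/02_indicators.R` prints these):

```
DR: yield 15.3 Mg/ha, energy in 53 GJ/ha, NEY 172 GJ/ha, NER 4.2, GWP 16795 kg CO2e/ha, GWPi 1100 kg/Mg, net return 1127 $/ha
MR: yield  7.7 Mg/ha, energy in 27 GJ/ha, NEY  86 GJ/ha, NER 4.2, GWP  7217 kg CO2e/ha, GWPi  937 kg/Mg, net return 1018 $/ha
RR: yield 13.2 Mg/ha, energy in 36 GJ/ha, NEY 158 GJ/ha, NER 5.4, GWP  9810 kg CO2e/ha, GWPi  745 kg/Mg, net return 2325 $/ha
```

Ratoon rice attains the highest energy ratio, the lowest GHG intensity
and roughly double the net return of the other systems — the pattern the
benchmarks describe.

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic survey -> results/survey.csv
Rscript analysis/02_indicators.R    # per-field indicators
Rscript analysis/03_compare.R       # summaries + ANOVA/LSD letters
Rscript analysis/04_regressions.R   # within-system and pooled OLS fits
```

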