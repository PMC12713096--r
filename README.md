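# soilstoich

Four-decade changes in soil C:N:P stoichiometry across cropland profiles.

Legacy soil surveys (such as the 1980s second national inventories)
describe profiles by **genetic horizons** — variable-thickness layers
with one measurement each — while modern resampling campaigns measure
fixed depth intervals (0–20, 20–40, 40–60, 60–100 cm). `soilstoich` is
for soil biogeochemists and agronomists who want to compare elemental
stoichiometry between such eras. It provides:

* **Depth harmonization** — per element, the horizon midpoint data are
  fitted with linear, logarithmic ($c = a + b\ln d$), exponential
  ($c = a e^{bd}$) and power ($c = a d^b$) regressions; the form with the
  highest original-scale $R^2$ is selected and evaluated at the layer
  midpoints 10, 30, 50, 80 cm.
* **Conversion uncertainty** — a within-profile residual bootstrap
  (B = 1000): resample regression residuals, refit the selected form,
  re-predict the layers; report the mean relative change with a
  percentile 95% CI, *directional stability* (% of replicates matching
  the point estimate's sign), and the sensitivity to ±2 cm horizon
  boundary perturbations.
* **Molar stoichiometry** — C:N, C:P, N:P with absolute and relative
  (Δ, %) changes between eras, whole-profile aggregation, layer stocks,
  and equivalent-soil-mass (ESM) corrected comparisons that remove
  bulk-density artifacts.
* **Nutrient-input and climate accounting** — annual and cumulative C/N/P
  inputs from straw, root + stubble residues, manure and mineral
  fertilizer using national-mean crop coefficients (straw moisture 14%;
  straw C 399/444/418 g/kg for wheat/maize/rice; root ratios
  0.30/0.26/0.30; topsoil root fractions 0.753/0.851; stubble ratios
  0.15/0.03/0.056); accumulated temperature and precipitation, Bio4/Bio15
  seasonality, and relative AET change.
* **Driver attribution** — iterative VIF screening (threshold 5),
  random-forest permutation importance (500 trees, 100-permutation
  significance test, OOB R²/RMSE/NRMSE/CV(RMSE)), partial correlation
  with confounder control, logarithmic baseline-dependence thresholds
  $x^* = e^{-a/b}$, and one-way ANOVA with Tukey HSD letter groupings.
* **A synthetic-data generator** with full ground truth (paired-era
  profiles, management ledgers, climate series), so the whole pipeline is
  testable end to end without any download.

## Worked example

Thirty synthetic sites with the default planted era effect (topsoil C:P
enrichment fading to subsoil depletion), harmonized, bootstrapped and
summarized:

```r
library(soilstoich)
cfg    <- synth_config(n_sites = 30, seed = 101)
report <- run_pipeline(cfg, B = 500, seed = 202)
print(report)
#> Soil C:N:P stoichiometry change report (30 sites, B = 500)
#>
#> Cross-site mean relative changes (%) by layer:
#>  ratio  layer point_mean   ci_lo   ci_hi dir_stability_pct impact_flag
#>     cn   0-20     25.054  17.553  40.836             100.0  negligible
#>     cn  20-40     13.819  11.245  17.362             100.0    moderate
#>     cn  40-60     -2.200  -5.692   7.573              64.2  negligible
#>     cn 60-100    -26.459 -30.443 356.478              79.2  negligible
#>     cp   0-20     33.879  29.039  37.516             100.0    moderate
#>     cp  20-40     26.538  24.475  29.836             100.0 substantial
#>     cp  40-60      5.071   2.700  16.021             100.0    moderate
#>     cp 60-100    -18.460 -21.763 495.922              73.4  negligible
#>     np   0-20     14.002  11.230  16.997             100.0    moderate
#>     np  20-40     11.963  10.058  14.218             100.0 substantial
#>     np  40-60      8.697   7.082  12.352             100.0 substantial
#>     np 60-100     14.246  11.517  23.651             100.0    moderate
```

Reading the C:P rows: the topsoil ratio rose by about +34% (CI
[29.0, 37.5], every bootstrap replicate positive) while the 60–100 cm
layer fell by about −18% — the planted depth-dependent pattern, with the
deep layer's wide CI upper tail reflecting the instability of
extrapolated exponential fits near the concentration floor. Layer
contrasts with Tukey letters:

```r
report$groups$layer$summary
#>    group       mean       se  n letter
#> 1   0-20  33.878533 3.018417 30      a
#> 2  20-40  26.537535 2.220135 30      a
#> 3  40-60   5.070634 2.522553 30      b
#> 4 60-100 -18.459963 4.724826 30      c
```

The two upper layers share a letter (not separable at α = 0.05); the
mid and deep layers differ from them and from each other. Individual
stages are plain functions: `fit_depth_models()`, `select_best_model()`,
`residual_bootstrap()`, `molar_ratios()`, `esm_adjust()`,
`cumulative_inputs()`, `climate_summary()`, `vif_screen()`,
`rf_permutation_importance()`, `log_threshold()`, `layer_anova()`. A
thin command-line wrapper lives at `inst/scripts/run_pipeline.R`.

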