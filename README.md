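# thermotrans

Analysis toolkit for common-garden **transplant experiments along
tropical elevation gradients**, built for the question behind
thermophilisation of Andean forests: when montane tree species are
planted at, and beyond, the hot extreme of their thermal range — and
lowland species at their cold extreme — how do survival and growth
respond to the displacement from each species' thermal optimum?

It is aimed at plant ecologists and biostatisticians working with
occurrence-based thermal niches, repeated tree censuses and site
weather series.

## What it computes

* **Species thermal distributions** from occurrence records (after
  grid-cell deduplication, elevation QC against a DEM, and 5%/95% tail
  trimming): thermal optimum *T*<sub>opt</sub> = mean MAT, thermal
  spread *T*<sub>SD</sub>, mean coldest/warmest-month temperatures, and
  the cold (10th–25th percentile of *T*<sub>min</sub>) and hot
  (75th–90th percentile of *T*<sub>max</sub>) extremes.
* **Montane/lowland classification** via a two-group k-means partition
  of (temperature, elevation) thermal space; the breakpoint is the
  midpoint of the cluster centers (≈ 18 °C / 1825 masl for the Andean
  reference cloud), montane iff *T*<sub>opt</sub> < breakpoint.
* **Growth**: relative growth rate
  RGR = [log(*D*<sub>i</sub>) − log(*D*<sub>0</sub>)]/(*t*<sub>i</sub> − *t*<sub>0</sub>)
  in mm mm⁻¹ yr⁻¹; scaled growth rate
  SGR = RGR<sub>ij</sub>/max(RGR<sub>j</sub>); thermal displacement
  index TDI = (MAT metric − *T*<sub>opt</sub>)/*T*<sub>SD</sub>
  (negative when the species optimum is warmer than the site).
* **Survival**: Kaplan–Meier product-limit curves and Cox
  proportional-hazards fits (Breslow ties, damped Newton, monotone-
  likelihood detection) with site as covariate.
* **Inference**: Welch t / Welch ANOVA, type-II two-way ANOVA, Tukey
  HSD, and the headline random-intercept mixed model
  `SGR ~ TDI × group + (1 | family)` fit by profiled REML, with
  marginal/conditional R².
* **Synthetic data** with known ground truth (`scenario_truth()`,
  `gen_occurrences()`, `gen_weather()`, `gen_census()`,
  `gen_thermal_space()`) emulating the full study design, so the whole
  pipeline runs and is testable with no downloads.

Reference tables for the 15 study species (thermal parameters,
botanical families, wood density) and the three experimental sites
(MAT and percentiles) ship in `inst/extdata/` and load via
`species_thermal_reference()` / `site_climate_reference()`.

## Worked example

Simulate the default scenario, compute growth metrics, and fit the
SGR ~ TDI mixed model (the generating slopes are −0.08 montane /
+0.07 lowland):

```r
library(thermotrans)

truth  <- scenario_truth(seed = 42)
census <- gen_census(truth, seed = 42)
growth <- compute_sgr(growth_records(census))

ref <- species_thermal_reference()
agg <- aggregate(sgr ~ species + site, data = growth, FUN = mean)
agg$group  <- ref$group[match(agg$species, ref$species)]
agg$family <- ref$family[match(agg$species, ref$species)]
sites <- site_climate_reference()
agg$tdi <- compute_tdi(sites$mat[match(agg$site, sites$site)],
                       ref$t_opt[match(agg$species, ref$species)],
                       ref$t_sd[match(agg$species, ref$species)])
lmm_fit(agg)
#> SGR ~ TDI x group mixed model (REML, family random intercept)
#>   n = 34 observations, 9 families
#>               term estimate     se
#>  intercept_lowland   0.8769 0.0347
#>  intercept_montane   0.8660 0.0159
#>      slope_lowland   0.0586 0.0070
#>      slope_montane  -0.0749 0.0054
#>   variance components: family 0.00095, residual 0.00216
#>   R2 marginal 0.849, conditional 0.895; REML loglik 40.040
#>   slope difference: 0.1335 +/- 0.0089 (p = 2.601e-51)
```

Only 34 of the 45 species × site cells appear because no montane tree
survives the hottest site — the montane slope (−0.075 ± 0.005) and the
lowland slope (+0.059 ± 0.007) recover the generating growth law, with
opposite signs: montane growth declines as sites warm past the optimum,
lowland growth declines as sites cool below it. Survival shows the same
asymmetry:

```r
rec <- build_survival_records(census)
cox_fit(rec[rec$species == "Quercus humboldtii", ], reference_level = "14C")
#> Cox proportional-hazards fit (Breslow ties): n = 72, events = 38
#>   covariate 'site', reference level '14C'; converged
#>       coef exp(coef)     se flagged
#> 22C 0.6443    1.9047 0.5578  FALSE
#> 26C 2.6314   13.8933 0.5280  FALSE
#>   log partial likelihood: -133.3683
```

i.e. for this montane oak the death hazard roughly doubles at the
22 °C site and is ~14× higher at 26 °C than at the site closest to its
thermal optimum. `run_pipeline()` chains all stages (niche →
classification → growth → survival → inference) from the three input
tables and writes every intermediate table plus a reproducibility
manifest.

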