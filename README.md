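# chumphen

Migration phenology of Chum salmon (*Oncorhynchus keta*) under
sea-surface-temperature regimes, at the southern limit of the species'
North Pacific range.

Chum return to the eastern and southern coastal waters of Korea each
October–December and enter rivers once the upper-layer SST falls below
about 20 °C. This package implements, as a tested pipeline over daily
regional SST and catch series, the analysis chain a fisheries-phenology
study of that system needs — and, because such catch data are rarely
deposited, a synthetic-data generator with the same statistical structure
so every estimator can be validated by parameter recovery. It is intended
for quantitative ecologists working on temperature-cued migration timing.

The pipeline has four analytical stages:

1. **SST regime typing.** For each region-year, the crossing day
   `d* = min{d : SST_d < 20 °C}` within the 92-day window (day 0 =
   Oct 1). Years are classified from crossing-day anomalies into three
   types: **T1** (whole coast cools earlier than average), **T3** (later
   than average), **T2** (the north cools earlier than the south by ≥ 7
   days, regardless of the overall sign).
2. **Phenology statistics.** The median date of migration timing
   (MDMT) — the first day the running cumulative catch exceeds 50 % of
   the seasonal total — at the coast and in the river, and the coastal
   residence time `riverine MDMT − coastal MDMT`.
3. **Mixed-model comparison.** Three candidate structures per response,
   compared by AIC = 2k − 2 logLik on maximum-likelihood fits:
   `y ~ T`, `y ~ T + (1|region)` (lme4), and `y ~ T × region`, with Wald
   *t* contrasts between regimes.
4. **Thermal response.** Catch pooled into 1 °C SST bins per region ×
   regime and normalised; quadratic `y = b₁ + b₂x + b₃x²`, exponential
   and logistic curves compared by AIC/MSE; the quadratic peak
   temperature is the vertex `−b₂/(2b₃)` (requires `b₃ < 0`).

## Worked example

Run the full pipeline on the built-in 13-season scenario (3 T1, 5 T2 and
5 T3 years, with a 4-day T2 arrival advance injected):

```r
library(chumphen)
cfg <- pipeline_config(preset = "mixed-13yr", seed = 42)
rp  <- run_pipeline(cfg)

head(rp$labels, 4)
#>   year label overall_anomaly ns_gap
#> 1 2006    T1          -7.538  -5.33
#> 2 2007    T3           4.295  -7.00
#> 3 2008    T1          -8.038  -6.33
#> 4 2009    T2           0.462  10.00
```

Every year is typed from its crossing-day anomalies (days, relative to
each region's climatology); 2009 is T2 because the south lagged the north
by 10 days. The model comparison for coastal MDMT:

```r
rp$lme$coastal_mdmt$comparison
#>   structure                     formula   logLik  k     AIC selected
#> 1         1                y ~ SST_type -213.244  4 434.489    FALSE
#> 2         2 y ~ SST_type + (1 | region) -202.695  5 415.389    FALSE
#> 3         3       y ~ SST_type * region -183.775 19 405.550     TRUE

subset(rp$lme$coastal_mdmt$contrasts, term == "T2 - T1" & is.na(region))
#>      term region estimate    se df     t       p marker   tier
#> 7 T2 - T1   <NA>    -2.92 0.868 60 -3.37 0.00133      * p<0.01
```

The T2 years' coastal arrival is estimated ~3 days earlier than T1 (the
generator injected −4; a single 13-year realisation carries ~0.9 days of
Monte-Carlo error). Note the marker convention is the inverted scheme
used in this study system's reports (`*` = p < 0.01, `**` = p < 0.05);
the `tier` column is the unambiguous reading. Quadratic peak temperatures per
region × regime:

```r
head(rp$nla$peaks, 4)
#>   region regime     family peak_sst
#> 1    CR1     T1 polynomial    16.71
#> 2    CR1     T2 polynomial    16.66
#> 3    CR1     T3 polynomial    19.97
#> 4    CR2     T1 polynomial    16.76
```

The step-by-step version of this analysis lives in `analysis/01_simulate.R`
through `analysis/05_thermal_response.R`; run them in order from the
repository root and each writes its tables under `results/` and prints
what it found. The methods vignette
(`vignettes/chum-migration-phenology.Rmd`) documents the models,
assumptions, tunables and known limitations.

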