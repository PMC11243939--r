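# radtransfer

Data reduction and radioecological analysis for gross-beta counting
campaigns that determine **Sr-90 activity concentrations in cultivated soil
and crops**, and for the soil-to-plant transfer modelling built on them.

Sr-90 (half-life 28.8 y) is determined by radiochemically separating its
Y-90 daughter (64.2 h) and counting it on a gas-flow proportional counter.
The package implements the full computation chain used by such monitoring
campaigns:

* **Activity estimation** — `A = (R − R₀)·e^{ln2·t/T½} / (ε·ηₛ·η·m)` in
  Bq/kg dry mass, with the Y-90 decay correction back to separation time,
  the quadrature uncertainty budget (reported at coverage factor 2), and
  the Currie-type minimum detectable activity
  `MDA = (2.71 + 4.65·√(R₀t₀)) / (ε·ηₛ·m·tS)`; results below the detection
  threshold are left-censored (`"<bound"`), never zeroed.
* **Transfer factors** — `TF = A_crop / A_soil` per plant organ, paired by
  plot and year; censored crop cells give undefined TFs rendered `/`;
  frequency histograms of TF by organ.
* **Exchange-based uptake model** — `TF_mod = k·α_ex / (K_c·CEC)`, its
  inverse, calibration of the uptake coefficient `k` (median or least
  squares), and a pedotransfer estimate of CEC from humus and clay.
* **Field statistics** — per-field property averages (with the zero-
  imputation convention for missing CaCO3), Pearson screening with
  significance tiers, one-way ANOVA and Tukey HSD.
* **Synthetic campaigns** — a generator with known truth (lognormal plot
  activities declining across years, organ partition root > leaf > stem >
  grain, Poisson counting at ε = 0.35 and 5400 s) used to demonstrate that
  the estimator is unbiased and its 2-sigma intervals cover at ~95 %.

The printed tables of a three-year campaign on two chernozem fields
(6 + 10 plots; winter wheat, maize, soybean, rapeseed) ship as plain-CSV
fixtures, and the package reproduces the published transfer-factor and
model-agreement tables from them.

## Worked example

```r
library(radtransfer)

fx <- load_campaign_fixtures()                       # printed campaign tables
tf <- build_tf_table(fx$crop_activity, fx$soil_activity)
subset(tf, year == 2013 & site_code == "R1")
#>   site_code year    crop_type         organ        tf defined
#> 1        R1 2013 winter_wheat          root 0.5771812    TRUE
#> 7        R1 2013 winter_wheat rest_of_plant 0.1711409    TRUE
```

The winter-wheat root on plot R1 in 2013 took up 1.72 of the 2.98 Bq/kg in
its soil — a transfer factor of 0.58 after the two-decimal report rounding,
matching the published cell. Auditing the whole table:

```r
cmp <- compare_tf_tables(tf, fx$tf_printed)
sprintf("exact: %d/%d cells, max |diff| = %.2f", cmp$n_exact, cmp$n_defined, cmp$max_abs_diff)
#> [1] "exact: 128/130 cells, max |diff| = 0.01"
```

128 of 130 defined cells reproduce exactly; the 8 censored maize-grain
cells reproduce as `/`. The model side: with the leached-chernozem
parameters (K_c = 2.1, α_ex = 0.7, CEC = 30 cmol/kg), an uptake
coefficient of 11.7 gives `model_tf(11.7, 0.7, 2.1, 30)` = 0.13, and the
per-site mean model/experiment ratios recompute as

```r
head(model_agreement(fx$agreement_printed), 3)
#>   site_code n_years mean_ratio
#> 1        R1       3  0.9518717
#> 2        R2       3  0.8394449
#> 3        R3       3  0.9730159
```

i.e. the model tracks the experimental transfer factors within a few tens
of percent (printed column: 0.94, 0.84, 0.97). A full desk run —
`run_campaign_reproduction("out/")` — writes the TF table, agreement table,
frequency histogram and field averages, and lists every cell that differs
from the printed tables. `run_synthetic(campaign_config(), seed = 1,
replicates = 200)` runs the generator-to-recovery pipeline instead.

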