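---
title: "Methods: Sr-90 counting data reduction and soil-crop transfer modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sr-90 counting data reduction and soil-crop transfer modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtransfer)
```

## The problem

Radiostrontium (Sr-90, half-life 28.8 y) deposited on agricultural soil
enters the food chain through root uptake. Monitoring campaigns determine
its activity concentration in soil and crop organs by radiochemical
separation of the short-lived daughter Y-90 (half-life 64.2 h) followed by
gross-beta counting, and summarise plant availability as the soil-to-plant
transfer factor (TF). This package implements that computation chain as
reusable, tested functions: counting-record reduction, censoring at the
detection limit, TF tables, a steady-state exchange model of uptake, the
campaign statistics, and a synthetic-campaign generator used to validate
the estimators.

## Activity estimation

For a counting record with sample rate $R$ and background rate $R_0$ (1/s),
counted $t_S$ and $t_0$ seconds, a time $t$ hours after Y-90 separation,

$$A = \frac{(R - R_0)\, e^{\ln 2\, t / T_{1/2}}}
          {\varepsilon\, \eta_s\, \eta\, m} \quad [\mathrm{Bq/kg\ dry}],$$

with counting efficiency $\varepsilon$ (0.35 for the reference detector),
chemical yield $\eta_s$, method yield $\eta$ and dry mass $m$ (kg). Times in
the exponent are in hours, matching the daughter half-life; the detection
limit below uses seconds so that Bq/kg emerges from counts. A negative net
rate is clamped to zero and flagged censored (reported bounds are never
negative).

The combined standard uncertainty multiplies $A$ by the quadrature sum of
the relative components (net rate, decay exponent via
$\delta T_{1/2} = \ln 2\, t\, \Delta T_{1/2}/T_{1/2}^2$, efficiency, yields,
mass); the half-life term defaults to zero when no half-life uncertainty is
supplied. Reported intervals use a coverage factor of 2 (~95 %); the
expansion is applied only at reporting, never propagated.

The Currie-type detection limit is

$$MDA = \frac{2.71 + 4.65\sqrt{R_0 t_0}}{\varepsilon\, \eta_s\, m\, t_S}.$$

As written this is a measurement-date quantity: it contains neither the
Y-90 decay-correction factor nor the method yield. Because the reported
activity *is* decay-corrected, the censoring decision compares the activity
against $MDA \cdot e^{\ln 2 t/T_{1/2}}/\eta$ — the same detection threshold
expressed on the activity's reference basis. `minimum_detectable_activity()`
itself stays verbatim; the reference-basis conversion happens in
`reduce_counting_records()`. A censored result reports the threshold as its
bound, participates in no ratio or mean, and renders as `"<bound"` (or `"/"`
in TF tables).

Y-90 ingrowth after separation is $1 - e^{-\ln 2 t/T_{1/2}}$; at 14 days it
is `r round(ingrowth_fraction(336), 4)`, which is why parent-daughter
equilibrium is conventionally assumed after a two-week wait.

## Rounding in report tables

Printed campaign tables round at two decimals. We round on the *decimal*
value (after clearing binary noise at the ninth decimal) and resolve exact
ties half-even. This choice was made by auditing the shipped tables: their
four decimal-tie average cells (2.735, 0.135, 1.345, 0.125) print as 2.74,
0.14, 1.34 and 0.12 — exactly decimal half-even, whereas half-up would
mis-render two of them. A `"half-up"` mode remains available. Note that
naive `round()` on doubles reproduces neither (2.735 is stored below its
tie).

## Transfer factors and censoring policy

`TF = A_crop / A_soil`, dry-mass basis, paired strictly by plot and year. A
censored crop activity yields an *undefined* TF — substituting 0 or MDA/2
would bias organ means low or high, and the published convention renders
such cells `/`. Frequency distributions of TF use half-open bins of width
0.05 (resolving the two-decimal print resolution without empty-bin
artefacts); the published "about 40 %" modal relative frequency refers to
per-organ histograms, and the package reproduces it as the mean of the
per-crop-per-organ modal frequencies (0.39 for wheat + maize), not as one
pooled histogram (which gives 0.23).

## The exchange model

The steady-state soil-solution-plant model treats plant-available Sr-90 as
the exchangeable fraction competing with Ca$^{2+}$ for exchange sites:

$$TF_{mod} = \frac{k\, \alpha_{ex}}{K_c\, CEC},$$

with $\alpha_{ex}$ the exchangeable fraction (used as a fraction of 1: the
adopted value 0.7 is only consistent with that reading, despite a "%" unit
label in some descriptions), $K_c$ the Sr/Ca selectivity, $CEC$ the cation
exchange capacity (cmol/kg), and $k$ a plant uptake-efficiency coefficient.
As printed the relation is dimensionally open — $k$ absorbs the residual
cmol/kg — and no correction is guessed (`model_k_units()` states the
audit). The adopted parameter sets are (2.1, 0.7, 30) for the leached
chernozem field and (1.9, 0.7, 32) for the chernozem field.

The source tables never print $k$ or its estimation procedure, so the
model's table of $TF_{mod}$ values is not independently reproducible; the
model is validated through the agreement ratio $TF_{mod}/TF_{exp}$ instead.
`calibrate_k()` estimates $k$ from experimental TFs by inverting the model
per observation and taking the median within a grouping (median rather than
mean: the per-observation $k$ inherits the right-skew of low-activity
years); an `"lsq"` option minimises the squared TF residuals, which for
this linear model is the mean. Calibrating per site-year reproduces the
experimental column exactly (ratios 1), and the package's acceptance check
asserts that those reproduced per-site mean ratios stay within the printed
span [0.70, 1.40]. Calibrating one $k$ per site (median over its three
years) is also supported but fails that band at two sites (mean ratios 2.24
and 2.16) — both driven by 2015 maize stem TFs of 0.03-0.05 that are 3-5
times below the site's other years, which a single steady-state $k$ cannot
track. This is a real limitation of a per-site constant-$k$ model, not of
the implementation.

The experimental TF used in the agreement table is the above-ground
vegetative one: the "rest of plant" TF for wheat and rapeseed, the stem TF
for maize and soybean. This rule is inferred — it matches every printed
cell — and is documented as such.

When CEC is not measured, `pedotransfer_cec()` maps humus (%) and clay (%)
linearly to CEC. The original pedotransfer coefficients are not printed in
the source; the shipped defaults (9.4 + 2.0 OM + 0.52 clay) are artifact
defaults fixed once so that the two fields' printed average humus and clay
reproduce their adopted CEC values (30.1 and 32.1 vs 30 and 32 cmol/kg).
Organic-matter input is the humus column, not total organic carbon — a
documented convention.

## Field statistics

Per-field averages are arithmetic column means; missing CaCO3 cells
(carbonate-free plots) are zero-imputed for the average rows (the printed
convention) but excluded by default elsewhere — a storage-level zero would
silently corrupt correlations. Pearson screening uses the product-moment
coefficient with the exact t-transform p-value (n-2 df) and tiers at
0.05/0.01/0.001; ANOVA and Tukey HSD are the classical `stats` procedures
behind a stable interface. Whether the published correlations were computed
per plot (n = 6/10) or per plot-year (n = 18/30) is not stated; both are
possible by passing the corresponding table.

Re-deriving the published between-field ANOVA tiers from the printed
activity tables succeeds for the root comparison (p < 0.001) and for soil
over all plot-years (p < 0.01), but not for soil restricted to
winter-wheat plot-years (p = 0.14) or the rest-of-plant fraction
(p = 0.26): the original analysis used triplicate raw measurements that are
not printed. The tests therefore assert only the reproducible comparisons.

## The synthetic campaign generator

`campaign_config()` defaults *are* the study conditions: 16 plots, three
years, first-year mean soil activity 2.5 Bq/kg with lognormal plot
dispersion (sigma = 0.2, matching the printed plot-to-plot range of
1.24-3.74 Bq/kg), an annual decline factor 0.85, organ partition
(root 0.5, leaf 0.25, stem 0.12, grain 0.10; 0.13 for the combined
"rest of plant" of wheat/rapeseed) ordered root > leaf > stem > grain,
counting efficiency 0.35, 5400 s counts, background 0.01 cps, chemical
yield 0.6-0.9 and dry masses 0.3-0.7 kg. A latent per-plot sorption factor
(lognormal, log-sd 0.2) scales all of a plot's TFs and loads positively on
clay, humus and hygroscopic humidity, inducing the qualitative
soil-property correlations; no mechanistic fidelity is claimed.

Two timing parameters are distinguished deliberately: `ingrowth_wait_h`
(336 h — the two-week parent-daughter equilibration before separation,
recorded for protocol realism) and `count_delay_h` (24 h — the
separation-to-counting delay that enters the decay correction). Using
336 h as the *counting* delay would raise the activity-basis detection
threshold ~38-fold and censor entire campaigns, which contradicts both the
reported detection limits (0.33/0.04 Bq/kg) and the observed censoring
pattern (grain cells only).

Counts are Poisson draws at the rate implied by inverting the activity
estimator, so the reduction chain can be validated against known truth:
over 200 replicate campaigns the estimator is unbiased (within Monte-Carlo
error) and the $A \pm 2\Delta A$ intervals cover the truth at 95.5 %
(nominal 95.45 % for 2-sigma). In the generator the calibration constants
are known exactly, so the synthetic uncertainty budget contains only the
counting term; adding systematic components would overcover by
construction. One RNG stream drives a campaign; campaigns are reproducible
bit-for-bit from (config, seed).

What passing these tests shows — and does not show — about real data: they
validate the arithmetic and the statistical calibration of the estimators
under the assumed model (Poisson counting, lognormal plot variation,
multiplicative organ partition). They cannot validate assumptions the
generator does not emulate: foliar uptake, spatial autocorrelation,
weather-driven deposition, or non-Poisson instrument effects.

## Numerical choices and degenerate inputs

Problem sizes used by the shipped checks: $10^4$ replicates for
unbiasedness and model inversion, 200 campaigns (~38,000 intervals) for
coverage, 1,000 random calibrations for detection-limit monotonicity, 30
site-years for uptake-coefficient recovery. Degenerate inputs are errors,
not guesses: zero soil activity, all-censored TF sets, empty report tables,
non-positive TF in the model inverse, negative predicted CEC. Equality
comparisons against printed two-decimal cells round both sides and compare
at the ninth decimal to keep binary noise out of the audit.

## Known limitations

* Two printed TF cells differ from the recomputation by one unit in the
  last place (0.76 vs 0.75; 0.10 vs 0.09) — consistent with the source
  rounding activities before printing; the pipeline reports them in its
  discrepancy ledger rather than absorbing them.
* Four printed per-site mean agreement ratios cannot be recovered within
  0.02 from the printed cells (the source averaged unrounded
  intermediates); the reproduction run flags them.
* The uptake model is steady-state and root-pathway only; no
  multi-compartment kinetics or time-dependent uptake.
* Raw count rates, yields and masses of the real campaign are not public,
  so raw-level reduction is validated synthetically; the published average
  detection limits are used as plausibility context only.
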