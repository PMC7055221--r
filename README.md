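# phoskin

Analysis of renal inorganic phosphate (Pi) excretion kinetics during
intravenous phosphate loading, for renal physiologists working with timed
urine collections and midpoint plasma samples (the classical titration
design, here parameterized for the acidotic rabbit — a pseudo-ruminant
whose kidneys conserve phosphate and whose extrarenal routes dispose of
most of an infused load).

## What it computes

Per collection and per timepoint, the derived renal quantities:

* excretion rate `E = V_u · U_Pi / Δt` (µmol·min⁻¹)
* filtered load `F = f_uf · GFR · P` (µmol·min⁻¹)
* fractional excretion `FePi = 100 · E / F` (%)
* tubular reabsorption `R = F − E` (µmol·min⁻¹)

Across the titration, the saturation-kinetics (threshold-linear) model of
tubular reabsorption

```
E(P) = max(0, g · (P − θ)),   g = GFR_Pi,   θ = TmPi/GFR,   TmPi = g · θ
```

is fitted by an exhaustive-grid hinge least squares with bootstrap
confidence intervals, plus a direct plateau estimate of TmPi from
saturated collections and allometric scaling to metabolic body weight
(`TmPi / BW^0.75`). A mass-balance module partitions the infused load into
renal excretion, extracellular accumulation (with expanding distribution
volume) and the residual extrarenal elimination flux. A forward simulator
of the loading protocol (single ECF pool, threshold-linear kidney, linear
extrarenal clearance, lognormal measurement and between-animal
variability) generates synthetic cohorts with known truth so the whole
pipeline is testable by parameter recovery.

See `vignettes/phosphate-loading-kinetics.Rmd` for the models,
assumptions, numerical choices and limitations.

## Worked example

Simulate a 6-animal cohort under the standard protocol (120 µmol·min⁻¹
infusion, 15-minute collections, 105-minute loading) and re-estimate the
renal parameters:

```r
library(phoskin)

sim <- simulate_cohort(simulation_config(rng_seed = 42))
fit <- bootstrap_fit(sim$dataset, n_boot = 500, seed = 42, plasma_cv = 0.10)
fit
#> Threshold-linear titration fit (hinge_grid/cohort_means)
#>   GFR_Pi (slope):      14.60 mL/min
#>   TmPi/GFR (threshold): 3.549 mmol/L
#>   TmPi:                51.8 umol/min
#>   points: 7 (6 above threshold); SSE 94.5
#>   95% bootstrap CIs (500 resamples, 0 degenerate):
#>     gfr_est       [9.76, 27.07]
#>     threshold_est [2.14, 4.44]
#>     tm_pi_est     [21.80, 113.08]
```

The slope of the supra-threshold titration line estimates the
phosphate-derived GFR (generating value 16.3 mL·min⁻¹), the hinge location
estimates the renal threshold TmPi/GFR (generating 3.48 mmol·L⁻¹), and
their product the transport maximum (generating 56.7 µmol·min⁻¹); all
three generating values fall inside the bootstrap intervals, whose width
honestly reflects a 6-animal cohort with 20% between-animal spread.

The per-timepoint kinetics table behind the classical summary:

```r
tab <- build_kinetics_table(sim$dataset, gfr = fit$gfr_est)
round(as.data.frame(tab)[, c("time_min", "filtered_mean", "excreted_mean",
                             "fe_pi_mean")], 1)
#>   time_min filtered_mean excreted_mean fe_pi_mean
#> 1      0.0          31.7           0.0        0.0
#> 2      7.5          52.2           2.9        6.3
#> 3     22.5          76.8          24.0       30.9
#> 4     37.5          95.0          46.5       49.7
#> 5     52.5         106.3          50.0       47.2
#> 6     67.5         106.2          61.1       59.0
#> 7     82.5         114.4          62.9       59.7
#> 8     97.5         127.5          70.7       57.8
```

Fractional excretion climbs from ~0% at baseline toward ~60% at the end
of loading even though the filtered load ends up near the infusion rate —
the signature of strong tubular conservation plus a non-renal disposal
route, which `extrarenal_series()` quantifies as the mass-balance
residual. `run_full_analysis()` chains reading, fitting, the table and
the mass balance into a report bundle (`table.csv`, `fit.json`,
`balance.csv`, `report.txt`) that states every defaulted assumption.

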