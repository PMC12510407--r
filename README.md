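# chpwater

Simulation and analysis toolkit for quantifying **choroid plexus (ChP)
water density** from high-resolution proton density-weighted MRI.

The ChP secretes cerebrospinal fluid and is increasingly imaged
quantitatively (perfusion, structure), yet its water density — a
calibration constant in every ASL perfusion model — has historically been
*assumed* equal to gray matter or blood rather than measured. The method
implemented here measures it with a ratio calibration: acquire a proton
density-weighted scan (long TR, short TE, with a driven-equilibrium DRIVE
module to keep the protocol time-efficient), take the mean signal in a ChP
ROI and a nearby periventricular white-matter ROI, and compute

```
rho_ChP = rho_WM * S_ChP / S_WM,        rho_WM = 0.70 mL/mL (literature)
```

The arbitrary scanner gain cancels in the ratio. Because no real scans can
ship with a package, `chpwater` generates the full study in silico with
known ground truth — periventricular digital phantoms driven by the
spin-echo signal equation `S = A·C·(1 − e^(−TR/T1))·e^(−TE/T2)` with a
DRIVE steady-state factor and Rician noise, cosinor-structured actigraphy
`E(t) = α(1 + cos(πt/f + φ))`, and a repeated-measures scan schedule — and
runs the complete analysis:

* **signal model** — closed-form spin-echo and DRIVE steady-state signals,
  protocol-bias and density-error propagation
  (`spin_echo_signal()`, `drive_steady_state()`, `protocol_bias()`,
  `ratio_bias()`)
* **synthetic cohort** — phantoms + truth masks + actigraphy + schedule
  (`make_cohort()`, `make_phantom()`, `make_actigraphy()`,
  `write_cohort()`)
* **quantification** — ROI means and the ratio calibration
  (`quantify_cohort()`, `quantify_nifti()`, `chp_water_density()`,
  `wm_sensitivity()`)
* **rhythmometry** — bounded multi-start cosinor fits and circadian time
  correction (`fit_cosinor()`, `circadian_correct()`)
* **perfusion** — single-compartment pCASL quantification and the
  water-density error sweep (`pcasl_perfusion()`, `m0a_from_tissue()`,
  `perfusion_error_sweep()`)
* **statistics** — mixed model with subject random intercepts, adjacent
  epoch contrasts, Spearman/Kendall rank tests
  (`fit_density_time_model()`, `rank_correlations()`)
* **pipeline** — `run_study()` orchestrates all of it from a single
  `study_config()` and master seed.

Everything is data-frame-first and pipe-friendly; fitted objects support
`tidy()`/`glance()`, and result tables have `autoplot()` methods.

## Worked example

```r
library(chpwater)
library(dplyr)

study <- run_study(study_config(), seed = 42)
study
#> ChP water-density in-silico study (seed 42 )
#>   grand mean density: 0.900 +/- 0.050 (n = 60, range 0.775-0.997)
#>   per-epoch density mean (SD): 0.896 (0.053), 0.903 (0.048), 0.909 (0.043), 0.891 (0.060)
#>   Spearman rho (clock time) = 0.008, p = 0.95
#>   perfusion error over 35-75 mL/100 g/min: 1.16 to 2.49
```

The grand mean over the 60 circadian scans recovers the ~0.895 mL water/mL
ChP level encoded in the per-epoch truth distributions, with the ~0.05
between-subject spread; the rank test finds no time-of-day relationship
(none is simulated); and propagating the measured density into pCASL
quantification shows the cost of assuming ChP and blood water densities
identical: 1–2.5 mL/100 g/min over physiological perfusion.

```r
filter(study$epoch_table, quantity == "rho_chp")
#> # A tibble: 4 × 8
#>   epoch quantity     n  mean     sd median   min   max
#>   <int> <chr>    <int> <dbl>  <dbl>  <dbl> <dbl> <dbl>
#> 1     1 rho_chp     15 0.896 0.0528  0.900 0.794 0.990
#> 2     2 rho_chp     15 0.903 0.0479  0.893 0.840 0.997
#> 3     3 rho_chp     15 0.909 0.0432  0.917 0.827 0.976
#> 4     4 rho_chp     15 0.891 0.0596  0.902 0.775 0.990
```

Individual pieces compose directly:

```r
sweep <- perfusion_error_sweep(f_actual = seq(35, 70, by = 5))
range(sweep$abs_error)
#> [1] 0.9776536 1.9553073

cohort <- make_cohort(n_subjects = 4, epochs = 2, n_repro_subjects = 0,
                      seed = 1)
quantify_cohort(cohort) |> select(scan_id, epoch, rho_chp, true_density)
```

See `vignettes/chpwater-methods.Rmd` for the models, default parameters,
and the design decisions behind the generator.

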