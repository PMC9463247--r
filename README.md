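# sirlic

Calibration and evaluation of **signal-intensity-ratio (SIR) methods for
estimating liver iron concentration (LIC)** from 1.5 T spin-echo MRI, with
paraspinal muscle as the reference tissue.

MRI estimates LIC indirectly: storage iron accelerates T1/T2 relaxation and
T2\* decay, so liver signal falls with iron. The SIR statistic
SI<sub>L</sub>/SI<sub>M</sub> (mean liver ROI signal over mean muscle ROI
signal) cancels the arbitrary scanner gain and maps to LIC through a
log-linear calibration, ln LIC = a + b·(SI<sub>L</sub>/SI<sub>M</sub>) with
b < 0. The usable range of any such method ends where liver signal hits the
Rician noise floor; shortening the echo time from 25 ms to 12 ms postpones
that collapse and extends the upper measuring limit from ≈ 30 to ≈ 100 mg/g
dry weight, and the repetition time can then be tuned to minimise
calibration variance. `sirlic` is aimed at quantitative-MRI methodologists
who want that whole analysis chain as tested, reusable R code:

* a longitudinal iron-loading **cohort simulator** (13 subjects, 81
  spin-echo examinations with same-day biopsy by default; spin-echo and
  multi-echo gradient-echo forward models, Rician ROI noise, lognormal
  biopsy sampling error with 19% CV);
* ROI statistics, the SIR, and **background censoring**;
* **R2\*** fitting from multi-echo GRE series with tail-echo truncation;
* **Passing–Bablok regression** (rank-based CIs, exact Kendall-score
  quantiles for n ≤ 30) with the **Cusum linearity test**;
* calibration fitting/inversion and the **measuring-range** computation;
* **TR adjustment** (quartic correction polynomial, identity at
  TR = 684 ms) and **calibration transfer** with the self-correction
  identity check;
* **Bland–Altman** agreement (absolute and percent scales, LoA CIs);
* a **heteroscedastic linear mixed model** (per-TR exponential variance
  function, subject random intercepts) with pointwise SD curves and TR
  selection.

## Worked example

```r
library(sirlic)

cohort <- simulate_cohort(default_dose_schedules(), rng_seed = 7)
cohort
#> Simulated SIR cohort: 13 subjects, 81 examination records
#>   biopsy LIC range: 0.49 to 205.3 mg/g
#>   acquisitions: SE 25/560

kept <- censor_low_signal(cohort, floor = 25)$kept   # 53 exams survive
cal  <- fit_calibration(kept, predictor = "sir")
cal
#> Calibration curve (log_linear_sir, TE 25 / TR 560 ms)
#>   ln LIC = 4.5026 + (-3.6613) * ratio
#>   valid LIC range: 0.494 to 32.9 mg/g
#> Passing-Bablok regression (n = 53)
#>   slope     -3.6613  (95% CI -4.4689 to -3.0944)
#>   intercept 4.5026  (95% CI 4.1458 to 5.0280)
#>   Cusum linearity: stat 0.674 -> linearity not rejected
```

The negative slope is the iron effect: each 0.1 drop in the liver/muscle
ratio multiplies the LIC estimate by e^0.366 ≈ 1.44. The Cusum statistic
(0.674 < 1.36) retains the linearity premise of the rank-based fit.
Inverting the curve and comparing against biopsy:

```r
est <- predict_lic(cal, kept$ratio)
bland_altman(est, kept$lic_biopsy, scale = "percent")
#> Bland-Altman agreement (percent scale, n = 53)
#>   bias 3.364%  (95% CI -9.257 to 15.984)
#>   LoA  -86.380 to 93.107%
#>   ...
```

Bias near zero says the calibration is centred; the wide limits of
agreement reflect the simulator's deliberately noisy study conditions
(19% biopsy sampling CV, scanner gain and muscle-T1 variability). The
echo-time effect on the measuring range:

```r
m <- default_relaxation_model()
measuring_range(m, acquisition_params("SE", 25, 560), floor = 25)  # 25.6 mg/g
measuring_range(m, acquisition_params("SE", 12, 560), floor = 25)  # 97.5 mg/g
```

`run_full_replication(run_config(seed = 1))` chains the whole analysis —
legacy-TE calibration and agreement, R2\* route, extended-range TE 12
calibration with the ≥ 115 mg/g exclusion, per-TR stratified R², mixed-model
TR selection, and the calibration-transfer identity check — and can persist
every table (CSV) and fit (JSON) to an output directory.

See `vignettes/sir-lic-methods.Rmd` for the models, the reasoning behind
every default, and known limitations.

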