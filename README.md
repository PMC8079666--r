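# fdm3pool

Quantitative myelin imaging from the complex multi-echo gradient-echo
(mGRE) signal, built as a fully simulatable pipeline. The package is
aimed at quantitative-MRI methodologists who want a tested, end-to-end
implementation of the frequency-difference-mapping (FDM) + three-pool
approach to callosal myelin measurement: synthetic raw data with known
ground truth, the phase-processing chain, the compartmental fit, and the
test–retest and patient–control statistics that sit on top of it.

## The model

White-matter mGRE signal is a superposition of myelin-water (`m`),
intra-axonal (`a`) and extra-axonal (`e`) water pools,

```
S(t) = f_a exp((i omega_a - R2*_a) t) + f_e exp(-R2*_e t) + f_m exp((i omega_m - R2*_m) t)
```

with the extra-axonal pool as frequency reference. Because the
short-lived myelin pool carries the largest (positive) frequency offset,
the *phase* of the total signal evolves non-linearly with TE; frequency
difference mapping isolates exactly that microstructural component by
removing the TE-independent (RF) phase and the linear-in-TE (static
field) phase per pixel. Magnitude and FDM curves averaged over each
callosal segment are then fitted jointly by bounded non-linear least
squares, yielding the myelin water signal fraction `f_m` (a myelin
proxy) and the myelin–axonal offset difference `delta omega / 2 pi`
(susceptibility / g-ratio sensitive). Reproducibility is summarised by
discrete Fréchet distances between FDM curves and by coefficients of
variation across visits, compared across segments with a modified
signed-likelihood ratio test; group inference uses group-by-age
regression and rank correlations with Bonferroni correction.

## Worked example

Fit the three-pool model to noiseless curves generated at the posterior
callosal segment's reference parameters:

```r
library(fdm3pool)

p <- segment_mean_params(3)          # posterior segment
p
#> <three_pool_params> f_m=0.16 f_a=0.42 f_e=0.42 | omega_m/2pi=27.3 Hz
#>   omega_a/2pi=-8.5 Hz | R2*_m=150 R2*_a=0 R2*_e=25 1/s

curves <- model_roi_curves(p, default_schedule())   # 25 echoes, TE 1.62-31.14 ms
fit <- fit_three_pool(curves)
fit
#> <fit_result> f_m=0.1600 f_a=0.4200 f_e=0.4200 (normalised) |
#>   delta_omega/2pi=35.80 Hz | resid=5.61e-15 | converged=TRUE
```

The fit recovers the generating parameters exactly: a myelin fraction of
0.16, an offset difference of 35.8 Hz, and a residual at numerical
precision. Fractions are reported sum-normalised because normalised
magnitude and FDM curves determine them only up to a common scale.

Test–retest behaviour across callosal segments, with visit noise graded
anterior-to-posterior as observed in vivo:

```r
rsim <- simulate_repro_study(seed = 1)       # 6 subjects x 5 visits x 3 segments
ft   <- fit_study_curves(rsim)
rp   <- analyze_reproducibility(ft)
rp$segment_cv   # mean per-subject CV%, segments 1/2/3 = anterior/mid/posterior
#>   segment cv_pct.delta_omega_hz cv_pct.f_m cv_pct.omega_a_hz cv_pct.omega_m_hz
#> 1       1                 27.30       43.0             22.63             33.92
#> 2       2                 17.73       36.5              9.66             24.00
#> 3       3                  4.93       11.8              8.04              6.44
rp$mslrt$f_m$p_value
#> 8.15e-07
```

Every metric is most reproducible posteriorly (e.g. `f_m` CV ≈ 12%
posterior vs ≈ 43% anterior), and the CV-equality test rejects strongly —
the pattern that motivates using the posterior segment for group
comparisons.

## The analysis workflow

The numbered scripts under `analysis/` run the full study narrative and
write their tables under `results/`:

1. `01_simulate.R` — phantom + raw multi-channel dual-polarity acquisition (NIfTI out).
2. `02_preprocess_fit.R` — polarity correction, coil combination, FDM, detrending, ROI fits.
3. `03_r2a_bias.R` — cost of fixing the intra-axonal decay rate at zero.
4. `04_reproducibility.R` — CV tables, Fréchet matrices, CV-equality tests.
5. `05_group_stats.R` — patient–control regressions and correlation family.

`run_full()` performs the same chain programmatically from a single seed
(optionally from a YAML config via `read_pipeline_config()`).

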