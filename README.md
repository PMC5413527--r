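# spectsync

Left-ventricular mechanical dyssynchrony analysis for ECG-gated myocardial
perfusion SPECT, with a digital gated-SPECT phantom and cohort-level
statistics for normal-database style studies.

## What it computes

In gated perfusion SPECT, regional counts track wall thickening through the
partial-volume effect. Fitting the fundamental cosine
`v(k) = a0 + a1 cos(2πk/N − φ1)` to each regional time-activity curve gives
the contraction **phase** φ1 (degrees of the cardiac cycle). From the
distribution of phases over all myocardial samples the package computes the
standard dyssynchrony indices:

- **PSD** — phase standard deviation (degrees), wrap-safe;
- **95% bandwidth** — shortest circular arc holding 95% of phases (degrees);
- **phase entropy** — normalized histogram entropy
  `E = −Σ f_i log f_i / log n`, 0 (complete order) to 1 (complete
  disorder), reported in percent;

and, on the AHA 17-segment model from fundamental + second-harmonic fits,
the time-to-end-systole family **MDTES**, **SDTES** and **DTES-LS**
(percent of cycle). A threshold-based cavity-volume estimator supplies
EDV/ESV/EF. The phantom generates gated short-axis studies with known
per-segment contraction delays, PSF blur and Poisson noise, so every stage
can be validated against ground truth; the cohort layer reproduces the
design of a normal-database study (per-sex normal limits, ANOVA and
Wilcoxon comparisons, correlation/regression against EDV and EF,
volume-matched sex contrast) on simulated data.

## Worked example

```r
library(spectsync)

spec  <- phantom_spec(edv_ml = 75, ef_true = 0.69, seed = 42)  # Poisson noise on
study <- generate_study(spec)      # 16 frames x 24 slices x 64 x 64 counts
fit   <- analyze_study(study)
fit
#> Gated SPECT dyssynchrony analysis
#>   phase samples: 396
#>   PSD 11.6 deg | 95% bandwidth 46 deg | entropy 63.6%
#>   MDTES 6.87% | SDTES 2.03% | DTES-LS +3.03%
#>   EDV 65.9 mL, ESV 19.3 mL, EF 70.7%
```

This synchronous phantom (all segmental delays 0) at clinical count levels
reads PSD ≈ 12°, bandwidth ≈ 46° — dispersion produced purely by Poisson
noise; the noise-free version of the same study reads PSD < 0.1°. The EF of
70.7% recovers the simulated truth of 69%. `summary(fit)` lists per-segment
TES; `plot(fit)` draws the phase histogram, volume curve, segmental TES and
segment TACs.

A delayed lateral wall is injected and recovered like this:

```r
d <- rep(0, 17); d[c(5, 6, 11, 12)] <- 36   # anterolateral + inferolateral, 10% of cycle
fit <- analyze_study(generate_study(phantom_spec(delay_deg = d, poisson = FALSE)))
fit$tes$dtes_ls_pct   # ~9.8 (truth 10)
fit$tes$mdtes_pct     # ~9.9 (truth 10)
```

Cohort-level replication of the normal-database design:

```r
tab <- run_cohort(cohort_spec(seed = 1))   # 36 male / 33 female subjects
report_cohort(tab)                          # means by sex, normal limits,
                                            # correlations, volume-matched contrast
```

A thin command-line wrapper over these functions is installed at
`inst/cli/spectsync.R` (subcommands `simulate`, `analyze`, `cohort`,
`report`).

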