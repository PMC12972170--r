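# eegreserve

Resting-state EEG (rsEEG) source analysis of **cognitive reserve** in
healthy ageing and the Lewy-body dementias (Parkinson's disease dementia,
PDD; dementia with Lewy bodies, DLB). The package implements, end to end,
the analysis design used to test whether educational attainment — the
standard cognitive-reserve proxy — modulates cortical alpha rhythms
*upward* in cognitively unimpaired elders (neuroprotection) and *downward*
in PDD (compensation), with a null effect in DLB.

## What it computes

- **Individualized frequency bands.** Per subject, the transition
  frequency TF (power minimum in 3–8 Hz) and individual alpha frequency
  IAF (maximum power peak in 6–14 Hz) define eight bands:
  delta = [TF−4, TF−2), theta = [TF−2, TF), alpha1 = [TF, mid),
  alpha2 = [mid, IAF) with mid = (TF+IAF)/2, alpha3 = [IAF, IAF+2),
  beta1 = [14, 20), beta2 = [20, 30), gamma = [30, 40).
- **Spectra.** Welch power spectral density (Hann window, one segment per
  2-s epoch, 0.5-Hz resolution over 0.5–45 Hz) after resampling to 256 Hz,
  0.1–45 Hz zero-phase filtering, common-average referencing and a
  programmatic artifact screen.
- **Cortical sources.** A three-shell spherical head model with an
  analytic Legendre-series leadfield, the eLORETA linear inverse (exact
  localization for noiseless point sources), grand-mean normalization of
  the voxel-by-bin solution, and collapse into 6 cortical macro-regions ×
  8 bands of log10 normalized current-density power.
- **Statistics.** Per-group mixed-design ANCOVA (Education × Band × ROI
  with sex/MMSE/unit covariates, LED for DLB), Duncan post hocs at the
  band-wise Bonferroni threshold 0.05/8 = 0.00625, Grubbs outlier
  screening, demographic tests (t / Fisher / Mann-Whitney), composite
  cognitive z-scores with Kruskal-Wallis and rank post hocs, Spearman and
  Pearson correlations, and interaction regressions with FDR-corrected
  simple slopes.
- **A synthetic cohort generator** (Healthy 27/27, PDD 30/45, DLB 21/29
  by education subgroup) that emulates the groups' spectral signatures
  (Healthy TF ≈ 5.6–5.8 Hz, IAF ≈ 8.9–9.0 Hz; PDD TF ≈ 4.5–4.7,
  IAF ≈ 6.7–7.2; DLB TF ≈ 4.7–4.8, IAF ≈ 7.0–7.6), demographics,
  clinical covariates and the signed education effects on alpha source
  amplitude, both as multichannel EEG (EDF export) and as a fast
  regional-activity archive.

## Worked example

```r
library(eegreserve)

cfg <- cohort_config()                    # published cohort conditions
profiles <- generate_profiles(cfg, seed = 1)
table <- simulate_activity_cohort(profiles, cfg, seed = 1)

healthy <- dplyr::filter(table, group == "Healthy")
fit <- rm_ancova(healthy)
dplyr::filter(tidy(fit), grepl("edu", term))
#>   term         stratum           df1   df2  statistic   p.value    pes
#> 1 edu          subject_id          1    48      0.234  6.31e-1  0.00486
#> 2 edu:band     subject_id:band     7   364      5.62   3.63e-6  0.0975
#> 3 edu:roi      subject_id:roi      5   260      1.37   2.37e-1  0.0256
#> 4 edu:band:roi Within             35  1820      0.911  6.19e-1  0.0172

duncan_posthoc(healthy)
#>   band   mean_low mean_high     diff     q  p.value threshold significant
#> 3 alpha1   0.0578     0.110 -0.0525  2.03  0.156      0.00625 FALSE
#> 4 alpha2   0.412      0.551 -0.139   3.71  0.0114     0.00625 FALSE
#> 5 alpha3   0.283      0.409 -0.126   5.22  0.000532   0.00625 TRUE
#> # ... (8 bands)
```

The Education × Band interaction is significant (F(7, 364) = 5.62,
partial η² = 0.098, the same medium-to-large range as reported for the
real cohort) and the Duncan contrasts localize the strongest effect to
alpha3, with higher alpha activity in the high-education subgroup — the
neuroprotective direction. In the PDD group the same pipeline finds the
reversed (compensatory) direction, and education-year trend regressions
on occipital alpha3 activity give a significantly negative slope for PDD
(−0.030 ± 0.007, p < 0.001) with no significant DLB trend:

```r
occ <- subject_activity(table, rois = "occipital", bands = "alpha3",
                        name = "occ_alpha3")
education_trend(occ, "occ_alpha3", by = "group")[, c("group", "slope",
                                                     "std.error", "p.value")]
#>   group      slope std.error   p.value
#> 1 Healthy  0.00380   0.00657 0.566
#> 2 PDD     -0.0299    0.00712 0.0000781
#> 3 DLB      0.00527   0.00669 0.435
```

The full signal-level route (simulate EEG → preprocess → spectra →
landmarks → eLORETA → normalize → collapse → statistics) is orchestrated
by `run_pipeline(pipeline_config(...))`, which also reads real EDF
recordings plus a metadata CSV in `mode = "edf"`.

## Documentation

The methods vignette (`vignettes/eegreserve-methods.Rmd`) describes the
models, the parameters and their defaults, what the synthetic generator
does and does not emulate, and the design decisions taken where the
published description is silent.
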