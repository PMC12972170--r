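---
title: "Methods: individualized-band EEG source analysis of cognitive reserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized-band EEG source analysis of cognitive reserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eegreserve` implements a complete resting-state EEG (rsEEG) analysis chain
for studying cognitive reserve — educational attainment as a proxy — in
healthy ageing and the Lewy-body dementias (Parkinson's disease dementia,
PDD, and dementia with Lewy bodies, DLB). This vignette explains the models
and procedures, the tunable parameters, what the synthetic cohort generator
does and does not emulate, and the design choices made where the design was
genuinely open.

## The analysis chain

1. **Harmonization.** Recordings are resampled to 256 Hz, band-passed
   0.1–45 Hz with zero-phase Butterworth filters (2nd-order high-pass,
   10th-order low-pass, each applied forward–backward), and re-referenced
   to the common average. Recordings below 256 Hz are rejected as below the
   minimum acquisition standard.
2. **Epoching and screening.** Data are cut into non-overlapping 2-s
   epochs (512 samples; 5 minutes gives 150 epochs). A programmatic screen
   stands in for expert visual artifact scoring: epochs fail on
   peak-to-peak amplitude (> 100 µV on any channel), on epoch-variance
   z-score (> 3 against the subject's own distribution), or on a 30–45 Hz
   over 1–30 Hz power ratio exceeding twice the subject's median (an EMG
   proxy; the upper edge is 45 Hz because standardized data are low-passed
   there). A warning is raised when fewer than 75% of epochs survive.
3. **Spectra.** Welch power spectral density with a Hann window, one
   segment per 2-s epoch and no overlap across epochs, window-power
   corrected, on a 0.5-Hz grid over 0.5–45 Hz.
4. **Individual frequency landmarks.** The transition frequency (TF) is
   the frequency of the channel-mean power minimum in 3–8 Hz; the
   individual alpha frequency (IAF) is the maximum local power peak in
   6–14 Hz. Degenerate spectra are flagged (`no_peak`, `boundary_hit`,
   `invalid`), never silently repaired.
5. **Individualized bands.** delta = [TF−4, TF−2), theta = [TF−2, TF),
   alpha1 = [TF, mid), alpha2 = [mid, IAF) with mid the TF–IAF midpoint,
   alpha3 = [IAF, IAF+2), and fixed beta1 = [14, 20), beta2 = [20, 30),
   gamma = [30, 40). Intervals are half-open; a spectral bin belongs to the
   band containing its center. When TF−4 falls below the 0.5 Hz floor the
   delta edge is clipped there and flagged.
6. **Forward model.** Three concentric spheres (scalp/skull/brain, radii
   100/92/87 mm, conductivities 0.33/0.0042/0.33 S/m) with electrodes at
   idealized 10-10 positions; dipole voxels on a 5-mm grid restricted to a
   cortical shell (60–80 mm radius, upper head), labeled with six
   macro-regions (frontal, central, parietal, occipital, temporal, limbic)
   by an angular sector rule. The gain matrix comes from the exact
   Legendre-series solution of the layered Poisson problem, truncated
   adaptively, and is average-referenced.
7. **Inverse.** eLORETA weights from the standard fixed-point iteration on
   per-voxel symmetric 3×3 blocks, with Moore–Penrose pseudo-inverses for
   the average-reference rank deficiency. Source power per voxel and
   0.5-Hz bin is `trace(T C T')` with `C` the sensor cross-spectral matrix
   — the full covariance, not only the PSD diagonal, because power through
   a linear spatial filter depends on inter-channel phase.
8. **Normalization and collapse.** Every voxel-by-bin power is divided by
   its grand mean over all voxels and all bins in 0.5–45 Hz (grand mean 1
   afterwards); the normalized solution is averaged within each of the
   6 regions × 8 bands and log10-transformed — the 48-cell table that is
   the unit of all statistics.
9. **Statistics.** Per diagnostic group: a mixed-design ANCOVA with
   Education (low/high) between subjects, Band and ROI within subjects,
   and sex, MMSE and clinical unit as covariates (LED replaces MMSE for
   DLB); band-wise Duncan post hocs at the Bonferroni threshold
   0.05/8 = 0.00625; Grubbs outlier screening at α = 0.001. Across groups:
   composite cognitive z-scores against the Healthy reference,
   Kruskal–Wallis with Dunn-type rank post hocs, Spearman correlation of
   MMSE with posterior alpha activity, interaction regressions with
   BH-FDR-corrected simple slopes, and per-group education-year trend
   regressions.

## Statistical model details

**Covariates in the repeated-measures design.** The covariates are
subject-constant, so in the error-stratified linear model they carry
degrees of freedom only in the between-subject stratum — the classical
ANCOVA treatment. Commercial packages are not explicit about their exact
covariate handling in repeated designs; this choice is the main fidelity
caveat and is stated here rather than hidden.

**Error strata.** `aov` with `Error(subject/(band + roi))` yields the
subject, subject-by-band, subject-by-roi, and within (subject-by-band-by-roi)
strata; Education-by-Band is tested against the subject-by-band stratum.
Greenhouse–Geisser epsilons are computed from the orthonormalized
within-cell covariance and reported alongside, but the uncorrected F is the
headline, matching the field's reporting convention.

**Duncan post hoc.** Education has two levels, so the Duncan multiple-range
test reduces to the unprotected range of two means: the p-value comes from
the studentized-range distribution with r = 2, which equals the pooled
two-sample t test on subject-level band means. Each band's p is compared
against 0.05/8.

**Grubbs.** Two-sided single-outlier test, detection only (no removal),
with the t-based critical value; degenerate zero-variance cells are flagged
rather than erroring.

**Effect size.** Partial eta squared is `SS_effect / (SS_effect +
SS_error)` within the effect's own stratum.

## The synthetic cohort generator

No public recordings exist for this design, so the generator is first-class
code. It emulates:

- **Sample structure**: Healthy 27/27, PDD 30/45, DLB 21/29 subjects in
  low/high-education subgroups (median-split proxy thresholds of 10, 8 and
  8 years).
- **Frequency landmarks**: TF and IAF are drawn from common within-group
  distributions (size-weighted means Healthy 5.7 / 8.95 Hz, PDD
  4.62 / 6.9 Hz, DLB 4.76 / 7.25 Hz; SDs recovered from the published
  standard errors), truncated to 3.2 ≤ TF ≤ 7.8, 6 ≤ IAF ≤ 13.5 and
  IAF − TF ≥ 1. The published education-subgroup landmark differences were
  explicitly non-significant, so the generator treats them as sampling
  variation rather than population structure: modeling them as distinct
  population means would create spurious education-by-band effects purely
  through band composition (each subject's bands follow their own
  landmarks), most visibly in DLB where no alpha effect exists.
  Per-subgroup means remain available through the `landmarks` argument.
- **Demographics and clinical covariates**: age, education years, sex
  ratios, raw and corrected MMSE, visual hallucination and RBD rates,
  UPDRS-III, disease duration and levodopa-equivalent dose per subgroup
  (e.g. PDD LED ≈ 608/606 mg, DLB LED ≈ 262/154 mg — the DLB imbalance is
  why LED is a DLB covariate), drawn from normal distributions with the
  published subgroup means and SE-derived SDs. The published
  disease-duration asymmetries (PDD Edu+ shorter, DLB Edu+ longer) are
  reproduced as configurable defaults without a generative claim.
- **Spectral structure**: each subject carries a (region, rhythm) source
  amplitude map. Patients show "slowing": delta/theta amplitudes ×1.8 and
  alpha ×0.73 relative to the Healthy template, whose alpha is
  posterior-dominant.
- **Education effects**: the alpha amplitude is multiplied by 1.30 in
  Healthy-Edu+, by 0.70 in PDD-Edu+, and is unchanged in DLB — the signed
  pattern under study (neuroprotective in Healthy, compensatory in PDD,
  null in DLB).
- **Cognition coupling**: in PDD, the attention/executive raw score tracks
  occipital alpha3 activity with slope 10 in Edu− and 0 in Edu+; patient
  domain scores sit 2 Healthy-SDs below the Healthy mean.

**Two realization paths.** The *signal path* (`simulate_subject`) renders
each subject as multichannel EEG: per region, a few dipoles carry white
noise spectrally shaped into strict-support envelopes — delta and theta in
their individualized bands below TF, an alpha component ramping from zero
at TF to a peak exactly at the IAF and decaying through IAF+2.5, beta at
14–25 Hz — on top of a 1/f background with a 6-Hz Lorentzian knee, projected
through the spherical leadfield with white sensor noise at SNR 5. The
strict-support envelopes are what make the TF trough and IAF peak
detectable: with these defaults the spectral stage recovers TF and IAF
within one 0.5-Hz bin for over 90% of subjects. The *archive path*
(`simulate_activity_cohort`) realizes the same amplitude maps directly as
48-cell activity tables — oscillator power split across the subject's own
bands (alpha 8/46/46% over alpha1–3, beta 60/40%), a 1/f background in all
bands, log-normal noise, and division by a bin-count-weighted grand mean
mirroring the pipeline's normalization. The archive path is used for
replicate-level statistical work where thousands of full signal
simulations would be pointless.

**Noise calibration.** The archive's variance components (per-band SD 0.10,
per-(region, rhythm) SD 0.10, per-cell SD 0.12 on the log10 scale) were
chosen so the configured alpha effects are reliably detectable at the
published sample sizes. An alternative calibration — matching the published
interaction effect size of η_p² = 0.09 exactly — makes the band-wise
post hoc a coin flip at n = 27/27, which would make any single study's
significant post hoc a lucky draw; we prefer a generator whose headline
pattern replicates, and accept an interaction effect size of ~0.08–0.12,
the same medium-to-large range. This is the generator's design target, not
a fitted quantity. Similarly, the PDD attention score's residual SD around
its alpha coupling (3.5 raw-score units) sits slightly below the published
regression residual SE (~4.3–4.4), where the published scale would give the
education-specific simple-slope pattern only ~70–75% single-study power.

**What the generator does not emulate.** Anatomical folding and
conductivity inhomogeneity (spherical shells only); genuine artifact
physiology (blinks and EMG bursts are stereotyped templates); eyes-open
data; longitudinal change; inter-site amplifier differences beyond what
harmonization removes. One knowing departure from the published pattern:
because grand-mean normalization is a zero-sum operation, a strong alpha
effect necessarily induces small opposite shifts in the other bands, and
with the generator's clean noise structure these occasionally reach the
Bonferroni threshold, whereas the published analyses report alpha-band
effects only. Passing tests on this generator therefore show the pipeline
recovers what was put in — not that real rsEEG satisfies the generator's
assumptions.

## Numerical choices

- Landmarks live on the 0.5-Hz grid; no sub-bin interpolation (matches the
  stated resolution). TF/IAF are detected on the channel-mean spectrum; a
  posterior-subset alternative is available via the `channels` argument.
- The shell-series transfer coefficients are solved per harmonic degree as
  a 5×5 linear system with radii normalized to the scalp (avoiding
  overflow), truncated when the worst-case tail bound falls below 1e-6.
- eLORETA default regularization is 1e-4 of the mean model-covariance
  eigenvalue; 0 gives the exact-localization regime. The fixed point
  iterates to a relative weight change below 1e-6, typically ~20
  iterations.
- Welch segments equal whole epochs (one 512-sample segment per 2-s epoch)
  — the only reading that gives exactly 0.5 Hz resolution.
- Whether the normalization pools conditions is read as per-subject,
  per-solution; `normalize_solution` guards against double normalization.
- Ties in Spearman correlations use mid-ranks with the t approximation;
  Fisher tests are two-sided by probability mass; Mann–Whitney uses the
  tie-corrected normal approximation.

## Problem sizes used in the tests

Module tests run on a coarse 18-mm source space (~150 voxels) and short
recordings (8–40 epochs); the localization oracle runs on an 8-mm space
(~1500 voxels); replicate-level statistical checks use the full published
sample sizes on the archive path (50 cohort replicates for the
education-by-band pattern, 100 PDD replicates for the simple-slope
pattern). These sizes are the package's own choice of a thorough but
proportionate test bed.

## Known limitations

- The sector parcellation cannot reproduce Brodmann-area boundaries; the
  limbic and parietal sectors in particular are geometric approximations,
  and voxel counts differ from atlas-based source spaces. External
  leadfields and parcellations can be supplied via the documented CSV
  exchange format (`read_leadfield`, `read_source_space`).
- Corrected MMSE is accepted as a supplied column, never computed
  (normative tables are not public).
- The covariate treatment in the repeated design is the classical one (see
  above); packages that let covariates interact with within-subject terms
  will give different within-stratum F values.
- No eyes-open condition, time-frequency analysis, connectivity metrics,
  or voxel-level statistics.
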