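Package: eegreserve
Title: Individualized-Band Resting-State EEG Source Analysis for Cognitive
    Reserve Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the effect of cognitive reserve (educational
    attainment) on resting-state EEG rhythms in Lewy-body dementias and
    healthy ageing. Implements individualized frequency-band partitions from
    the transition frequency (TF) and individual alpha frequency (IAF),
    Welch power spectra on 2-s epochs, a three-shell spherical-head EEG
    forward model, the eLORETA linear inverse with grand-mean normalization,
    aggregation into six cortical macro-regions by eight bands, and the
    full statistical battery (mixed-design ANCOVA with Duncan post hocs and
    band-wise Bonferroni correction, Grubbs outlier screening, demographic
    tests, composite cognitive z-scores, Kruskal-Wallis with rank post hocs,
    interaction regressions with FDR-corrected simple slopes). A synthetic
    cohort generator emulating Healthy, PDD and DLB groups stratified by
    education drives testing and power exploration without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
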