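Package: rcdpe
Title: Multiscale and Downsampling Permutation Entropy for Surface EMG
    Fatigue Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ordinal-pattern complexity analysis of uniformly sampled
    physiological signals, centred on the permutation entropy (PE) family:
    multiscale PE obtained by coarse-graining (MPE), its composite (cMPE)
    and refined composite (rcMPE) variants, and the downsampling variants
    (DPE, cDPE, rcDPE) in which scaled signals are disjoint decimated
    phases rather than overlapping block averages.  Includes spectral
    utilities linking the analysis scale to the effective bandwidth
    (Welch power spectral density, band-power ratios, moving-average
    filter cutoff), a generator of surrogate surface-electromyography
    (sEMG) fatigue cohorts, and a windowed fatigue-discrimination
    pipeline with repeated-measures ANOVA reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    car,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
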