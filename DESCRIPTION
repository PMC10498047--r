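Package: entrainR
Title: Entrainment Analysis of Drosophila Locomotor Activity Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether individual flies are entrained to a
    light cycle, for estimating free-running circadian periods under constant
    conditions, and for extracting and statistically assessing activity-peak
    phases from Drosophila Activity Monitor (DAM) beam-crossing recordings.
    Implements Savitzky-Golay smoothing of startle-contaminated activity
    series, the chi-square (Sokolove-Bushell) periodogram with significance
    line and rhythmic power, Morlet wavelet spectra with daily period
    estimates, skeleton-photoperiod and ramped-light entrainment
    classification, circular statistics (Rayleigh and V tests) for phase
    control, four-parameter logistic dose-response modelling of
    intensity-dependent period lengthening, and a ground-truth phase-oscillator
    simulator of fly locomotor activity with parametric and non-parametric
    light action, masking, startle transients and Poisson count emission.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
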