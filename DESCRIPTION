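Package: mechanopillar
Title: Quantitative Analysis of Mechanically Gated Currents Evoked by
    Elastomeric Pillar-Array Deflections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying mechanoelectrical transduction in
    chondrocytes and other adherent cells stimulated through elastomeric
    pillar arrays. Provides subpixel pillar-center localization by 2D
    Gaussian fitting and deflection measurement from before/during/after
    bright-field frames, deflection-to-force calibration for cylindrical
    elastomer pili via beam mechanics and Hooke's law, extraction of
    latency and mono-exponential activation/decay time constants from
    whole-cell current traces, binned stimulus-response statistics with
    per-cell thresholds and responder classification, Boltzmann fitting
    of high-speed pressure-clamp families (P50), calcium-imaging dF/F
    response scoring, exact nonparametric tests (Fisher, Mann-Whitney,
    variance-ratio F), and seeded synthetic-data generators that emulate
    every input class so the full pipeline is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
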