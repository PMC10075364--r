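Package: hippolfp
Title: Hippocampal LFP Analysis: State Segmentation, Band Power, Theta-Gamma
    Coupling and Sharp Wave-Ripple Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for laminar hippocampal CA1 local field
    potential (LFP) recordings in freely moving rodents. Segments sessions
    into behavioral states (exploration, grooming, wake immobility) from
    tracking speed, computes Welch power spectra with total-power-normalized
    band power, estimates theta-gamma phase-amplitude coupling via the
    mean-vector-length modulation index (comodulograms and time-resolved
    PAC), detects sharp wave-ripple events by dual-threshold ripple detection
    with sharp-wave co-detection, and fits random-intercept linear mixed
    models with Benjamini-Hochberg FDR-corrected post hocs. Ships a synthetic
    session generator with per-stage ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
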