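Package: eeglifespan
Title: Population-Scale Spectral Analysis of Consumer EEG Across Adulthood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying age- and sex-related trends in four-channel
    consumer EEG at population scale. Implements an artifact-gated
    preprocessing chain (notch and 2-36 Hz band-pass filtering, fixed-length
    epoching, epoch-power rejection, session-level exclusion and a
    first-five-clean-sessions cap), 1-Hz power spectra with canonical band
    powers, peak alpha frequency with explicit no-peak handling, and frontal
    and temporoparietal alpha asymmetry. Population age trends are fitted by
    weighted least squares on per-age cell means with centred age, quadratic
    age and sex-interaction terms, coefficient-identical to ordinary least
    squares on the individual-level data. A seeded synthetic-cohort generator
    renders raw sessions from a parametric 1/f-plus-alpha-bump spectral model
    with known age and sex trends, so the whole pipeline is testable without
    access to proprietary recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
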