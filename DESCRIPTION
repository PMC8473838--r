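Package: duetsync
Title: Behavioral and Inter-Brain Synchrony Analysis for Duet Hyperscanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-EEG (hyperscanning) recordings of
    paired music performance. Computes behavioral synchrony measures from
    tone-onset streams (quarter-note inter-onset intervals, signed and
    absolute duet asynchronies), frequency-tagged spectral entrainment at
    the duet performance rate (Welch power spectral density with local
    noise normalization and rate-aligned spectra), spatio-spectral
    decomposition (SSD) spatial filters for oscillation extraction,
    amplitude-envelope correlations between partners' brains with a
    surrogate re-pairing null, and a synthetic generator of coupled duet
    timing (phase-correction timekeeper model) and dual-brain EEG with
    known ground truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
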