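Package: cmrtools
Title: Comodulation Masking Release Analysis for Auditory Cortical Spike Trains
Version: 0.1.0
Authors@R:
    person("cmrtools", "authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for quantifying comodulation masking release (CMR) in
    populations of auditory cortical neurons. Implements a stimulus model for
    sinusoidally amplitude-modulated tone maskers with narrowband, incoherently
    modulated and comodulated flanking bands; an inhomogeneous-Poisson
    synthetic spike-train generator with planted condition effects for
    parameter-recovery testing; peristimulus time histogram construction;
    the signal-response (SR) statistic in pooled-SD units with per-cell and
    population neurometric threshold estimation; frequency response area
    mapping with dual-criterion region extraction and characteristic-frequency
    assignment; across-frequency interaction (AFI) onset metrics; bootstrap
    significance screening; and an end-to-end simulate-analyze-report
    pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
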