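Package: cycleshape
Title: Cycle-by-Cycle Waveform Shape and Phase-Amplitude Coupling Analysis of EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying non-sinusoidal waveform shape of neural
    oscillations in scalp EEG, cycle by cycle. Extracts per-cycle peak and
    trough sharpness and rise and decay steepness from band-delimited cycles
    of the raw signal, summarises them as sharpness, steepness, peak-to-trough
    and rise-to-fall ratios with a four-quadrant shape typology, and computes
    beta-phase/gamma-amplitude coupling as a normalized modulation index.
    Includes EEG preprocessing (demeaning, common-average and bipolar
    referencing, zero-phase FIR high-pass, artifact-interval bookkeeping),
    Welch spectral checks for oscillation presence, nonparametric paired and
    unpaired group statistics with false-discovery-rate control and effect
    sizes, and a synthetic-data generator producing non-sinusoidal
    oscillations over 1/f background with paired two-state cohorts, so the
    whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
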