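Package: phaselock
Title: Dynamic Phase-Locking State Analysis for BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Leading-eigenvector dynamics analysis (LEiDA) of regional BOLD
    time series: band-pass filtering and Hilbert instantaneous phases,
    per-timepoint phase-coherence matrices summarized by their leading
    eigenvector, k-means clustering into recurrent phase-locking states with
    Dunn-index model selection, event-locked condition masking with a
    hemodynamic lag shift, per-subject temporal state metrics (switching
    frequency, fractional occupancy, mean dwell time, switch probabilities),
    and permutation repeated-measures ANOVA with post hoc permutation t-tests
    and false-discovery-rate correction. Includes a synthetic multi-subject
    cohort generator with planted phase-locking states and event timelines
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
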