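Package: phonolab
Title: Phonation Analysis for Synthetic Larynx Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for bench-top phonation experiments on
    synthetic (silicone) larynx models. Provides a kinematic vocal-fold
    oscillation simulator with controllable asymmetry, closure, and
    cycle-to-cycle perturbation; segmentation of high-speed frame stacks
    into glottal area waveforms with a left/right hemiglottal split;
    cycle-based waveform parameters (periodicity, symmetry, closure,
    stiffness); acoustic measures (cepstral peak prominence,
    harmonics-to-noise ratio, jitter, shimmer) and subglottal-pressure
    measures; and a grouped nonparametric testing pipeline
    (Kruskal-Wallis screening with Mann-Whitney post hoc tests under
    Bonferroni correction) that summarises a full two-factor
    flow-rate-by-fiber-tension experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
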