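Package: respshape
Title: Cycle-by-Cycle Coupling of Respiration and Neural Oscillation Waveform Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how the waveform shape of individual breaths relates
    to the shape of respiration-locked neural oscillation cycles in
    intracranial recordings. Provides a seeded synthetic-data generator with
    known ground-truth coupling; preprocessing (anti-aliased resampling,
    bipolar re-referencing, respiratory low-pass, zero-phase Bessel band-pass
    and z-scoring); spectral screening of channels by magnitude-squared
    coherence against phase-randomized surrogates together with a spectral
    parameterization peak criterion; time-domain screening via epoch-averaged
    cross-correlation with a permutation null and a phase monotonicity index
    with a circular-shift null; two-stage extrema detection, greedy
    respiration-neural peak matching and per-cycle waveform feature
    extraction; and a hierarchical Bayesian within-between Student-t
    regression estimating standardized cycle-by-cycle shape coupling, with
    matched cycle-shuffled null models and airflow-versus-belt modality
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
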