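Package: msdyn
Title: Resting-State EEG Microstate Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: synthetic
    semi-Markov EEG generation with ground-truth sidecars, a preprocessing
    chain (band-pass/notch filtering, epoching, spherical-spline channel
    interpolation, amplitude-based epoch rejection, average referencing),
    global-field-power peak extraction, topographic atomize-and-agglomerate
    hierarchical clustering (T-AAHC) with cluster-validity criteria,
    polarity-invariant template backfitting with window smoothing and
    short-segment removal, microstate temporal parameters (duration,
    occurrence, coverage, global explained variance) and transition
    probabilities, and two-group inference with Bonferroni families,
    Cohen's d and scale-score correlations, including recomputation of
    group statistics from published summary moments.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
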