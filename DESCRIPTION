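Package: tonocortex
Title: Bedside EEG Assessment of Auditory Cortex Frequency Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-subject analysis of auditory event-related EEG aimed at
    evaluating the functional integrity of the auditory cortex at the
    bedside.  Implements automatic N100 detection by a t-CWT procedure
    (Mexican hat continuous wavelet transform, pointwise Student-t
    scalograms, Hotelling T-squared significance at the detected
    time-scale minimum) and detection of frequency-selective cortical
    processing by one-versus-one linear support-vector-machine
    classification of single trials with repeated four-fold
    cross-validation and permutation-test significance.  Includes a
    pseudo-random tone-burst stimulus protocol generator, a standard
    epoching/filtering/artifact preprocessing chain with spherical-spline
    channel interpolation, and a synthetic 10/10-montage ERP simulator
    (condition-dependent N100-like deflections in pink noise) so the whole
    pipeline can be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    kernlab,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
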