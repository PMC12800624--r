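Package: callcontext
Title: Context Coding and Playback Analysis of Primate Yawn Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for asking whether a graded primate call type
    carries information about the social context of its emitter, and whether
    receivers act on it. Implements acoustic feature extraction from mono WAV
    recordings (temporal, intensity, fundamental-frequency and formant
    measures), coefficient-of-variation coding indices (the Potential of
    Contextual Coding, PCC) with a three-step feature-selection procedure,
    linear discriminant classification with leave-one-out cross-validation
    assessed by exact binomial tests against class-proportion chance, and
    variable-contribution analysis. A companion simulator synthesises
    source-filter calls with context-dependent acoustic shifts and caller
    random effects, assembles playback stimuli and schedules under field
    constraints, and generates behavioural trial tables whose gaze counts and
    yawn responses follow zero-inflated Poisson and logistic mixed models;
    matching mixed-model fitters (Gauss-Hermite quadrature, random subject
    intercept) with likelihood-ratio tests, collinearity diagnostics and
    adjusted pairwise contrasts complete the inference side.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    glmmTMB,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
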