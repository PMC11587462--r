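Package: patternglare
Title: Habituation and Sensitisation Analysis of Sustained EEG Responses to
    Pattern-Glare Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of sustained ("DC-shift") EEG responses to striped
    pattern-glare stimuli. Provides a ground-truth synthetic generator for
    epoched multi-channel EEG with exponential habituation and sensitisation
    structure, preprocessing (FIR band-pass, average reference, baseline
    correction, amplitude-threshold artifact rejection, participant inclusion
    rules), the Pattern Glare Index contrast, questionnaire factor analysis
    with varimax rotation and Gram-Schmidt orthogonalisation, construction of
    factor-by-exponential-change design regressors at two time granularities,
    mass-univariate regression with cluster-based Monte-Carlo permutation
    inference over channel-by-time volumes, and reporting utilities
    (median-split grand averages, percentile-bootstrap confidence bands,
    cluster summary tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
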