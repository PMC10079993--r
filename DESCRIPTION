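Package: plinet
Title: Phase-Lag-Index Brain Networks and Compact CNN Classification for Oddball EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing phase-lag-index (PLI) functional
    brain networks from auditory-oddball EEG and for classifying subject groups
    with a compact convolutional network. Includes a three-group synthetic
    cohort generator with band-specific phase coupling, zero-phase band
    decomposition and epoching, PLI connectivity with proportional
    thresholding, binary graph metrics (degree, betweenness, clustering, local
    and global efficiency), one-way ANOVA with Tukey post-hoc comparisons on
    channel-mean connectivity, and a from-scratch compact CNN (temporal,
    depthwise-spatial and separable convolutions trained with Adam and
    decoupled weight decay) under subject-exclusive cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
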