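Package: plihub
Title: Phase Lag Index Connectivity and Betweenness Hub Analysis for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Band-limited functional connectivity and network-hub analysis for
    resting-state EEG. Implements phase lag index (PLI) estimation from
    Hilbert instantaneous phases of FIR band-filtered 5-s epochs, inverse-PLI
    weighted graphs with normalized betweenness centrality per electrode
    (Brandes accumulation with exact tie handling), and the group-level
    statistical layer: mixed repeated-measures ANOVA with Greenhouse-Geisser
    correction, Benjamini-Hochberg controlled post hoc t-tests per electrode,
    pre/post within-subject ANOVA, and Pearson correlations against clinical
    scores. A coupled-oscillator cohort simulator with plantable band-specific
    hubs, zero-lag common sources and 1/f background makes every stage
    verifiable end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    igraph
Config/testthat/edition: 3
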