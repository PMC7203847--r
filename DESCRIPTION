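Package: losslessr
Title: Lossless Quality-Control Annotation for Multi-Site Continuous EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staged, annotation-over-rejection preprocessing pipeline for
    continuous EEG. Channels, time periods, and independent components are
    flagged using robust windowed statistics, pooled study-level distribution
    envelopes, neighbor-correlation criteria (bridging, decoupling), and
    two-stage independent component analysis; all decisions are stored as
    editable sidecar annotations on unmodified raw data in a BIDS-EEG
    derivative tree. Includes a ground-truthed synthetic EEG generator,
    quality-control summary reports (time/channel/component accounting,
    spatial variance, pre/post power spectra), and a batch command-line
    front-end with a purge utility that applies reviewed annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
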