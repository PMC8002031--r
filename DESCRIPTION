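Package: msepls
Title: Multiscale Entropy and Task Partial Least Squares for Event-Related EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neural change during prolonged cognitive task
    performance from epoched multichannel EEG: event-related potential
    averaging with baseline correction, multiscale entropy (coarse-graining
    plus sample entropy) on single trials, and task partial least squares
    with permutation tests and bootstrap-ratio stability. Includes a
    synthetic-data generator (1/f background noise with planted ERP
    components and shifted-lognormal response times), trial-exclusion and
    chronological-segmentation utilities, and a repeated-measures ANOVA
    chain with Greenhouse-Geisser correction and generalized eta-squared.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
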