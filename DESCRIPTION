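Package: tilepeak
Title: Transcription-Factor Target Discovery from Promoter Tiling ChIP
    Arrays and Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based binding-event detection on two-color promoter
    tiling ChIP arrays, using the sonication fragment-length distribution
    to derive the expected single-event coverage shape, a grid search
    least-squares fit of peak center and fold enrichment, and empirical
    log-likelihood-ratio p-values from permutation nulls. Companion tools
    calibrate position-weight-matrix score cutoffs by background sampling,
    normalize one-color expression time courses by cyclic loess, test
    differential expression by permutation, and integrate binding with
    expression including Fisher's exact gene-set enrichment. A synthetic
    data generator with machine-readable truth tables supports end-to-end
    benchmarking with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
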