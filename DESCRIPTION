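Package: hicmat
Title: Hi-C Contact Matrix Construction, Correction and Analysis
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds binned Hi-C contact matrices from classified paired-end
    read records with per-category quality control, removes per-bin coverage
    biases by iterative correction (ICE), and derives the standard downstream
    summaries of chromosome conformation data: distance-decay curves,
    observed/expected, Pearson and covariance transforms, A/B compartment
    eigenvector tracks, TAD-separation scores with boundary and domain calls,
    virtual 4C viewpoint tracks and aggregate contact maps. Includes an
    in-silico restriction digestion model, readers and writers for SAM,
    4DN .pairs, BED and bedGraph text formats, a plain-text contact-matrix
    container, a seeded synthetic Hi-C generator with ground-truth sidecars
    for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
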