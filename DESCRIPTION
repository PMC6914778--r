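Package: dualreporter
Title: Dual-Reporter Decomposition of Cell-to-Cell Gene Expression Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions cell-to-cell variation in gene expression measured
    with pairs of fluorescent reporters into intrinsic noise, signaling
    (pathway) noise, and general protein expression capacity, using the
    two-reporter moment estimators of the intrinsic/extrinsic noise
    literature. Includes a generative lognormal simulator of per-cell
    image-cytometry tables with closed-form expectations for every variance
    bin, reading and validation of per-cell and per-animal measurement
    tables, a kinetic model of green-to-red fluorescent timer proteins for
    separating protein production from turnover, and a reproducible
    simulate-decompose-compare pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
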