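Package: mdgsea
Title: Multidimensional Gene-Set Enrichment Analysis via Logistic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-set enrichment analysis by logistic regression of set
    membership on one or two gene-level ranking statistics and their
    interaction. Fits the bivariate membership model by maximum likelihood,
    tests each coefficient with a Wald statistic, applies
    Benjamini-Hochberg correction within each coefficient family, and
    classifies every gene set into a taxonomy of enrichment patterns
    derived from the geometry of the fitted log-odds surface (plane or
    saddle). Includes readers for GMT and gene/term annotation files,
    ranking ingestion and alignment utilities, confidence-ellipse
    summaries, and a fully seeded synthetic-data and simulation harness
    for type-I error, correlation-bias and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
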