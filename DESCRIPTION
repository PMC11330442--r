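Package: unexploitr
Title: Discovery of Unexploited Disease Genes from Paired Expression Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering "unexploited" disease genes: genes
    with literature evidence of disease involvement that are nonetheless
    absent from gene-disease association databases (false negatives of the
    databases). Implements a vote-counting meta-analysis of paired
    stress/control expression (the ON-ratio/ON-score statistic), integration
    of multi-study disease DEG lists and TWAS evidence with provenance,
    offline classification of genes against local database snapshots,
    TWAS-or-multi-study candidate refinement, structured literature
    adjudication, and exact hypergeometric overlap statistics. Includes a
    synthetic-data generator that emulates the statistical shape of the
    real inputs so the whole pipeline is testable offline with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
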