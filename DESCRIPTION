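Package: oncodrug
Title: Network Analysis and Repurposing of FDA-Approved Anticancer Drugs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Catalog modeling and network-assisted analysis of the FDA-approved
    anticancer pharmacopoeia (1949-2014). Builds drug-cancer bipartite and
    cancer-drug-target tripartite networks with degree analytics, predicts
    novel drug-cancer associations by common-target guilt-by-association
    transfer and evaluates them against clinical-trial counts, and examines the
    genetics of drug targets: hypergeometric enrichment in cancer genes, a
    four-way gene-set partition, and somatic mutation-frequency comparisons
    across gene sets. Ships the curated drug, target, cancer-class, and
    trial-count tables as plain-text data, plus seeded generators for
    synthetic catalogs and mutation tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
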