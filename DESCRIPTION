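Package: mirnet
Title: MicroRNA Target Network Extraction and Canonical Network Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds molecular networks around predicted microRNA target genes
    and scores them against libraries of canonical pathway, disease, and
    pathological-event networks. Target predictions are filtered by miTG
    score, mapped onto a molecular-interaction knowledgebase, expanded by a
    one-hop neighboring network search, and compared with every canonical
    network using an upper-tail hypergeometric overlap statistic reported as
    a negative base-2 log score. Includes a synthetic-data generator that
    emulates a curated interaction knowledgebase, canonical-network library,
    and per-miRNA target predictions with tunable planted enrichment, so the
    whole pipeline is testable without proprietary resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
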