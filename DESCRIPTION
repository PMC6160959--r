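Package: pxea
Title: Proximal Pathway Enrichment Analysis for Network Endopharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactome-based proximity between gene sets with
    degree-matched null models, disease pathway spans, and a GSEA-like
    running-sum enrichment (PxEA) that scores drugs by the proximity of
    their targets to pathways shared across diseases. Includes
    overlap-based enrichment statistics, a multi-evidence disease-disease
    network (diseasome) builder, a random-walk-with-restart proximity
    alternative, and synthetic-data generators for benchmarking the
    robustness of proximity to noise in pathway annotations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
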