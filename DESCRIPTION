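Package: phosClue
Title: Knowledge-Guided Cluster-Number Selection for Temporal Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the most biologically informative partitioning of
    time-course phosphoproteomics data. Phosphosite temporal profiles are
    clustered by fuzzy c-means or classic k-means over a range of cluster
    numbers, and each partitioning is scored against a kinase-substrate
    annotation database: per-cluster kinase enrichment by one-sided Fisher's
    exact test, per-cluster minimum p-values combined across clusters by
    Fisher's combined probability test (chi-squared, 2k degrees of freedom),
    and summarized as an enrichment score -log10(P). The cluster number
    maximizing the restart-averaged score is reported as optimal. Includes a
    simulation framework (temporal profile templates, Gaussian site noise,
    synthetic kinase-substrate databases with controllable annotation noise),
    PhosphoSitePlus-style and GMT annotation parsers, position-specific
    scoring matrix motif scoring, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    optparse,
    stats,
    graphics,
    utils,
    tools
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
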