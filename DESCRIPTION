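Package: genesupport
Title: Genetic Support and Relative Success of Drug Development Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies how human genetic evidence differentiates the success
    of drug development programmes. Provides information-content-based
    ontology similarity (Resnik, Lin) for matching drug indications to
    genetically associated traits, source-specific filters for Mendelian,
    GWAS, colocalization, exome-burden and somatic-driver evidence,
    relative-success (risk ratio) statistics with Katz confidence intervals,
    Wilson proportion intervals, stratified Cochran-Mantel-Haenszel tests,
    ordinal and logistic trend models, and enumeration of the gene-by-
    indication universe with utilization and enrichment summaries. Includes
    a synthetic-data generator with known ground truth so the full pipeline
    is testable end to end without proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
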