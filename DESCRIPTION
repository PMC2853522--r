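Package: alphadom
Title: Domain Structure and Concerted Evolution of Alpha-Satellite
    Higher-Order Repeat Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing highly homogeneous human alpha-satellite
    higher-order repeat (HOR) arrays: monomer and HOR decomposition of raw
    array sequence, in-silico restriction analysis, consensus-anchored
    alignment of near-identical repeat copies, calling of diagnostic variant
    nucleotides (DVNs) versus sporadic mutations, CENP-B box scanning,
    segmentation of arrays into homogenisation domains with barrier and
    conversion-tract and crossover-duplicate inference, and comparison of
    repeat sets (homologues, CENP-A-associated versus bulk repeats) including
    a nearest-neighbour intermingling statistic. A forward-time simulator of
    tandem-array evolution under sporadic mutation, gene conversion and
    similarity-gated unequal crossover generates synthetic arrays and clone
    samples with ground-truth event logs, so that every stage of the pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
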