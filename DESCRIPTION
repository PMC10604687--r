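Package: orthonorm
Title: Normalized Cross-Species Orthology Store with Species Augmentation
    and a JSON Query Catalog
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ingests combined-orthology tab-separated files in the dialect
    published by model-organism data alliances into a normalized relational
    store (species, genes, algorithms, directed ortholog pairs, algorithm
    links), translates gene identifiers against a GeneWeaver-style external
    registry (gene, species, genedb tables), augments the store with species
    absent from the canonical source by decomposing externally supplied
    homology clusters into filtered pairwise orthologous relationships,
    aggregates the pairwise table back into homology clusters (incrementally
    or from scratch), and exposes the result through a fixed catalog of 50
    JSON query endpoints in six categories. Ships a deterministic synthetic
    fixture generator so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
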