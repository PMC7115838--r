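Package: coralsom
Title: Curation and Set Analysis of Coral Skeletal Organic Matrix Proteomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-search curation workflow for intra-skeletal (skeletal
    organic matrix) proteomes of stony corals. Applies a peptide-evidence
    acceptance rule to search-engine output, screens cross-species (human)
    contaminants by alignment statistics plus an exact shared-peptide rule,
    builds per purification-method and solubility-fraction detection
    matrices with full Venn/set summaries, classifies proteins by export
    mechanism (signal peptide, transmembrane span, GPI anchor) and by
    GO-derived functional category, and tests cross-proteome orthology
    overlap against chance with exact binomial and hypergeometric tails.
    Includes a seeded synthetic-data generator that plants ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
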