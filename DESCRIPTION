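Package: gprules
Title: Reconstruction and Evaluation of Gene-Protein-Reaction Rules for Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs Boolean gene-protein-reaction (GPR) rules for
    genome-scale metabolic models from offline snapshots of biological
    databases: metabolite entity resolution against compound dictionaries,
    reaction matching through a merged multi-source reaction store,
    subunit/isoform relationship mining from protein annotation text,
    curated complex sets, interaction networks and orthology groups, and
    assembly of the final Boolean expressions. Ships the full evaluation
    machinery used to benchmark reconstructed rules against curated models:
    truth-table equivalence with a configurable gene cap, Jaccard and
    normalized Hamming statistics, rule-class accounting, and flux-balance
    single-gene-deletion confusion matrices solved by linear programming.
    A deterministic synthetic-fixture generator provides complete organism
    snapshots with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    xml2
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
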