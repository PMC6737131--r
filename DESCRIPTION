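Package: egpath
Title: Essential-Gene Prediction on Metabolic Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts prokaryotic gene essentiality from KEGG Orthology (KO)
    annotations and multi-strain knockout panels. Parses KGML pathway maps into
    compound-reaction graphs, recovers "missing" essential genes (gap genes
    masked by paralogs, isozymes or alternative pathways) with a depth-first
    remapping search over the reaction score matrix, computes per-KO
    experimental essentiality scores (E_score) and annotation-group prediction
    scores (P_score), turns scores into binary essentiality calls, and
    evaluates calls with standard confusion-matrix metrics. Includes seeded
    generators for synthetic pathway maps, strain panels and annotation tables
    so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
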