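Package: enzymap
Title: Mapping Disease-Associated Enzymes onto a Pathway Hierarchy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates multi-source disease-gene association tables into a
    deduplicated germline union set, restricts it to enzymes (EC number or a
    Gene Ontology molecular-function term descending from catalytic activity),
    expands Reactome-style pathway annotations from leaves to hierarchy roots,
    classifies enzyme-disease associations (biunivocal, univocal,
    non-univocal) and diseases (monogenic/polygenic, type A/B by leaf-pathway
    cardinality), and builds the weighted co-occurrence network of pathway
    roots shared by diseases. Ships a constructive synthetic-data generator
    with a planted ground-truth manifest so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
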