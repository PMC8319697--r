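Package: litkg
Title: Mining Typed Biomedical Knowledge Graphs from Annotated Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning PubTator-formatted abstracts into a typed
    biomedical knowledge graph. Implements dictionary-based named-entity
    recognition over domain lexicons (diseases, symptoms, drugs, chemicals,
    Chinese patent medicines, herbs, ingredients, genes, pathways) with a
    corpus-level entity-frequency filter, sentence-level co-occurrence
    relation candidates, keyword-rule relation typing with a pluggable
    classifier fallback, confidence aggregation, knowledge-graph assembly
    with GraphML and Neo4j bulk-import export, text-mining evaluation
    metrics (precision/recall/F1, relation confusion matrices and the
    correct rate), and a seedable synthetic-corpus generator for offline
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
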