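Package: gosimnorm
Title: Annotation-Length-Aware Gene Ontology Semantic Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes fourteen Gene Ontology (GO) semantic similarity scores
    for protein pairs (Resnik, Lin, Relevance and Jiang term measures under
    average and best-match-average combination, plus term overlap, normalized
    term overlap, Dice, Cohen's kappa, graph information content and
    vector-space cosine), audits their dependence on protein annotation
    length with a randomized term-group null model, and removes that bias by
    a per-length-combination power transformation that standardizes scores
    against the null distribution. Includes OBO and GAF ingestion restricted
    to IS-A subsumption, information-content computation, complete-linkage
    clustering with hypergeometric enrichment under Benjamini-Hochberg false
    discovery rate control, and generators for synthetic ontologies and
    annotation corpora with controllable annotation-length bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    nortest,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
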