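Package: semphylo
Title: Semantic-Network Phylogenetics from Ontology Annotations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds functional phylogenies from gene-set annotations on a
    biological-process ontology. Per-species gene lists are translated into
    enriched ontology-term profiles by prioritized hypergeometric pathway
    analysis with permutation-based adjusted p-values; the ontology graph is
    standardized by trimming terms that exceed the upper percentiles of both
    structural information content (IC) and semantic value (SV), remapping
    trimmed terms to their most proximal retained ancestors; species are
    compared by a consensus (Resnik, XGraSM, AggregateIC) best-match-average
    group-wise semantic similarity, yielding distance matrices, Ward
    clustergrams, two-dimensional embeddings and clustering evaluation
    (homogeneity, silhouette). Conserved and kingdom-specific functional
    components are extracted by quasi-omnipresence screening, generic-ancestor
    aggregation and non-negative matrix factorization of the species-by-term
    association matrix, and arbitrary ontology-defined mechanisms can be
    evaluated as evolutionary markers with bias-controlled gene-set sizing.
    Includes a synthetic-data generator producing random ontologies and
    annotation corpora with planted kingdom structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
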