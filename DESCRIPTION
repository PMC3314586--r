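Package: GOsieve
Title: Weighted Gene Ontology Term Scoring for Protein Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfers Gene Ontology (GO) annotations to query proteins from
    sequence-similarity (BLAST-style) and domain (HMMER-style) search results.
    Retrieved GO terms are weighted by hit e-values, propagated to the
    ontology roots to form a per-protein term subgraph, clustered by Lin
    semantic similarity, filtered by a Z-score on cumulative weights and a
    Group Score, and ranked by a Total Score combining information content,
    internal confidence and evidence weight. Also provides the protein-centric
    precision/recall assessment protocols (exact-term and root-propagated
    matching) and a deterministic synthetic-benchmark generator so the whole
    pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
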