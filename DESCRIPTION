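Package: cumrank
Title: CumulativeRank Identification of Potential Super-Spreaders in
    Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies nodal spreading ability in undirected contact
    networks with the CumulativeRank algorithm, which combines a
    semi-local improved network constraint coefficient (INCC) built on
    LocalRank neighbourhood counts with a per-node tenacity score of the
    node's role in maintaining network connectivity. Includes SNAP-style
    edge-list input, benchmark centralities (degree, betweenness,
    eigenvector, LocalRank, PageRank), key-node identification by an
    iterative depth-first dfn/low rule, and a discrete-time all-contact
    SIR simulator for evaluating seed sets selected by each ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
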