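Package: netmet
Title: Network-Based Enrichment of Metabolite Lists on Hierarchical
    Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enrichment analysis for metabolomics that goes beyond a flat
    pathway list. A list of affected KEGG compounds is mapped onto a
    five-level hierarchical knowledge graph (pathways, modules, enzymes,
    reactions, compounds) and every node is scored by network propagation:
    heat diffusion on the undirected graph with a grounded boundary, or
    personalized PageRank on the upward-directed view. Raw scores are
    normalized against the permutation null of random compound inputs,
    either parametrically (z-scores through the exact first two moments)
    or by Monte Carlo simulation, yielding p-scores used to rank nodes.
    The top-ranked sub-network is reported with tabular and GraphML
    exports, with an optional filter that removes connected components no
    larger than expected under uniform random node sampling. Includes a
    KEGG REST builder with a file cache, a synthetic hierarchical graph
    generator for fully offline testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
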