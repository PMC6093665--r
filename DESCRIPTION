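Package: mpsearch
Title: Maximum Parsimony Search, Consensus and Taxon-Stability Tools for
    Discrete Morphological Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equally weighted maximum-parsimony analysis of discrete
    morphological character matrices in the TNT (xread) and NEXUS dialects:
    Fitch (unordered) and Farris (ordered, additive) character optimization,
    random-addition Wagner starting trees with TBR branch swapping,
    zero-length-branch collapsing (rule 1), strict (Nelsen) consensus,
    Bremer supports from suboptimal tree pools, positional-instability
    (wildcard) detection with reduced consensus, OTU merging and character
    re-scoring, exhaustive search oracles for small taxon sets, and a
    seed-reproducible matrix simulator with known generating trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
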