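Package: BridgeNet
Title: Network-Based Gene Prioritization with Cluster Hubs, Bridge Nodes
    and Boolean Pathway Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Expands a small set of seed genes into a weighted
    protein-protein interaction network from STRING-style evidence
    tables, detects cohesive overlapping clusters and their hub genes,
    ranks sparsely connected bridge nodes by bridging centrality
    (current-flow betweenness times the bridging coefficient) and by an
    annotation-relevance score, tests gene-set over-representation with
    the hypergeometric distribution under FDR control, combines
    expression evidence with Welch t-tests and the Stouffer Z-transform,
    and simulates treatment stimuli on KGML-derived signed pathways via
    Boolean networks converted to continuous (BooleCube/HillCube) ODE
    dynamics, ranking genes by state-switch frequency across Monte-Carlo
    simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
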