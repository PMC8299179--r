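Package: scaffnet
Title: Multi-Dimensional Hierarchical Scaffold Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scaffold-based analysis of screening libraries. Generates nine
    correlated molecular representations per molecule (basic, decorated and
    augmented scaffolds, each as concrete scaffold, any-atom framework and
    any-atom/any-bond wireframe), fragments them by exhaustive removal of
    internal chains, opening of fused rings and deletion of internal rings,
    builds an oriented framework/fragment network with Cytoscape-ready
    export, supports wildcard ("any atom"/"any bond") substructure queries,
    and annotates nodes with activity enrichment factors for
    structure-activity relationship analysis of high-throughput screens.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (used through ChemmineOB)
Config/testthat/edition: 3
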