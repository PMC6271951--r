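Package: oxascreen
Title: Combinatorial Amino-Oxazole Library Design and Virtual Screening
    Post-Processing for Biotin Carboxylase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational redesign of bacterial biotin
    carboxylase (BC) inhibitors built on the 2-amino-oxazole-5-carboxamide
    scaffold. Provides combinatorial enumeration of amino-oxazole derivatives
    from small organic building blocks with Tanimoto-based deduplication,
    Shannon-entropy conservation profiling of the ATP binding site across
    seven BC isoforms, post-processing of multi-isoform docking score tables
    (anchor-consistency filtering, joint-probability docking accuracy,
    SUM-rule consensus rank fusion, rank correlation), BEDROC early-enrichment
    analysis of building-block clusters, distance-based classification of
    protein-ligand contacts including halogen bonds, and seeded synthetic-data
    generators that emulate the docking stage so the whole pipeline is
    testable without an external docking engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
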