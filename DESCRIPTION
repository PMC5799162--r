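Package: anatnet
Title: Anatomical Network Analysis of Head and Neck Musculoskeletal Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for anatomical network analysis (AnNA) of musculoskeletal
    systems. Reads binary connectivity matrices over named anatomical units
    (bones, cartilages, muscles) together with node metadata, computes the six
    standard AnNA parameters (node count N, link count K, density D, mean
    clustering coefficient C, characteristic path length L, and degree
    heterogeneity H), detects anatomical modules by deterministic greedy
    modularity optimization, classifies modules (facial, laryngeal, vocal-fold,
    suprahyoid-tongue, postcranial, neurocranial), quantifies facial-module
    asymmetry and facial-muscle inclusion, and assembles cross-taxon comparison
    tables. A synthetic musculoskeletal-network generator with planted modules
    and mirrored left/right anatomy makes every pipeline stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
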