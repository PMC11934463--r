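Package: genesetwalk
Title: Latent Gene-Set Associations via Bipartite Graph Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Uncovers latent associations between biological terms (gene sets)
    by embedding a gene-term bipartite graph with node2vec-style biased random
    walks and skip-gram negative sampling. Term pairs are scored jointly by
    gene-set overlap (Jaccard index and hypergeometric significance) and by
    embedding distance; embedding hyperparameters are selected by internal
    clustering validation (silhouette, Davies-Bouldin); the closest pairs and a
    minimum spanning tree over terms summarise the global term-relationship
    structure; and ortholog-converted collections from a second species are
    projected into the frozen embedding space for cross-species nearest-term
    discovery. Reads and writes GMT gene-set collections and two-column
    ortholog tables, and ships seeded synthetic-data generators with planted
    module structure so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
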