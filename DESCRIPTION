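Package: popnet
Title: Population Networks and Super-Paramagnetic Clustering of Genome-Wide SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers fine-scale population structure from genome-wide SNP
    genotypes without prior ancestry information. Genotypes (PLINK text
    PED/MAP) or precomputed genetic distance matrices are turned into an
    allele-sharing distance matrix, a mutual k-nearest-neighbour population
    network, and an unsupervised partition of individuals obtained by
    super-paramagnetic clustering: a q-state Potts model with
    distance-dependent ferromagnetic couplings simulated by Swendsen-Wang
    cluster Monte Carlo across a temperature gradient. Spin-spin correlations
    yield per-temperature partitions, a cluster-stability hierarchy, and
    cluster-relationship matrices that are exported in visualization-ready
    formats (GraphML, SIF, Newick). Includes quality-control filters (call
    rate, minor allele frequency, exact Hardy-Weinberg test, duplicate
    detection), a Balding-Nichols population simulator with hierarchical
    divergence, and PCA with Horn's parallel analysis plus k-means with the
    Calinski-Harabasz criterion for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
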