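Package: phenonet
Title: Deep Phenotypic, Genotypic and Environmental Personality Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline that organizes temperament and character
    biclusters of a personality cohort into near-disjoint phenotypic
    networks and associates them with genotypic and environmental set
    networks. Implements consensus nonnegative matrix factorization (NMF)
    biclustering with cophenetic-correlation rank selection, exact
    hypergeometric and Fisher set-overlap testing with permutation nulls,
    bipartite network partitioning, well-being and ill-being health
    indices with ANOVA and Tukey HSD comparisons, ancestry stratification,
    cross-validated variance-explained estimates, and cross-cohort
    replication matching. Includes a synthetic-cohort generator with
    planted bicluster and network structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
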