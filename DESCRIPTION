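Package: mycodyn
Title: Succession Analysis of Phyllosphere Fungal Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing seasonal succession in leaf-associated
    (phyllosphere) fungal communities and its host-genetic drivers. Provides
    an OTU-table data model with decontamination against negative controls,
    cumulative sum scaling and Hellinger normalisation, Bray-Curtis
    distances, ordination (PCoA and nonmetric multidimensional scaling with
    monotone regression), permutational inference (sequential PERMANOVA with
    restricted permutations, multivariate dispersion homogeneity, Mantel
    tests), community trajectory geometry with a leave-one-OTU-out influence
    procedure, host-genetic association (Nei's pi distance, kinship,
    spectral REML pseudo-heritability, single-marker GWAS with SVD
    covariates), occupancy-ranked core-taxon selection, per-taxon time
    explainability mixed models, indicator species analysis, and
    compositional covariance-network analysis with Zi-Pi node roles. A
    synthetic successional-community generator with recorded ground truth
    supports end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    vcfR,
    cluster,
    withr
Config/testthat/edition: 3
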