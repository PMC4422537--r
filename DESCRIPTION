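Package: germcore
Title: Core and Mini Core Collection Construction for Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates germplasm core collections by geographic
    stratification, phenotypic UPGMA clustering and proportional random
    sampling, and extracts mini core collections that maximize a weighted
    combination of mean Modified Rogers' distance and pooled Shannon band
    diversity over dominant-scored SSR marker data. Provides the standard
    marker diversity statistics (Shannon information index, Nei expected
    heterozygosity, polymorphism information content), trait Shannon-Weaver
    indices, Jaccard and Modified Rogers distance matrices, UPGMA dendrograms
    with Newick export, and the statistical machinery used to compare a
    subset against its source collection (median equality test, class
    homogeneity test, Q-Q quantile comparison with plugin Kullback-Leibler
    distance, Fisher z correlation comparison, Mantel permutation test).
    Includes a calibrated synthetic panel generator emulating a multi-region
    mungbean germplasm collection with two subpopulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
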