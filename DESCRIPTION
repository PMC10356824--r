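Package: casoil
Title: Soil Quality and 16S Bacterial Community Analysis for
    Conservation-Agriculture Field Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-scenario conservation-agriculture
    soil studies combining soil chemistry and 16S rRNA amplicon community
    profiles. Implements alpha-diversity estimators (Shannon, Gini-Simpson,
    Chao1, ACE, Fisher's alpha) and exact hypergeometric rarefaction,
    Bray-Curtis beta diversity with principal coordinate analysis and the
    ANOSIM permutation test, a PCA-based minimum-data-set soil quality
    index with non-linear indicator scoring, Duncan's multiple range test
    with compact letter display alongside Kruskal-Wallis and Pearson
    correlation reporting, taxonomic aggregation and shared-OTU analytics,
    and a Dirichlet-multinomial community simulator that emulates a
    seven-scenario tillage-cum-crop-establishment experiment so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    biomformat,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
biocViews: Microbiome, Metagenomics, DiversityAnalysis, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
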