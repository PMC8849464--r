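Package: landgenr
Title: Landscape Genomics of Vector Populations: Differentiation, Outlier
    Scans, MLPE Models and Resistance-Surface Optimisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for landscape-genetic analysis of biallelic SNP data from
    structured insect (or other) populations sampled across a heterogeneous
    landscape. Provides population-genetic diversity and differentiation
    statistics (observed and expected heterozygosity, rarefied allelic
    richness, Nei FST, Hedrick G''ST, Meirmans standardised FST, hierarchical
    F-statistics with permutation tests), a three-method outlier-locus scan
    for habitat association (random-forest ranking with backwards purging,
    partial redundancy analysis loadings, and FST-heterozygosity null
    envelopes), maximum-likelihood-population-effects (MLPE) regression of
    pairwise genetic distance on geographic or effective distance, and
    resistance-surface optimisation: monomolecular transforms of landscape
    rasters, commute-time effective distances from the graph Laplacian, a
    genetic-algorithm search over transform parameters scored by MLPE
    log-likelihood, AICc model selection with site bootstrap, and
    circuit-theory current-density mapping. A synthetic-landscape generator
    with known resistance truth and known outlier loci supplies a
    ground-truth test harness for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    randomForest,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
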