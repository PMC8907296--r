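Package: scsEntropy
Title: Shape-Constrained Spline Normalization of Clonal Diversity Indices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Normalization of Shannon clonal-diversity indices for viral
    integration-site (IS) clonal-tracking data. Log-entropies are modelled as a
    sum of monotone-increasing, concave, optionally saturating B-spline effects
    of technical confounders (DNA amount, vector copy number, sequencing depth,
    pool size) plus unconstrained or shape-constrained factors of interest,
    fitted by restricted least squares via quadratic programming. Provides
    confounder-free rescaled entropies, cone-projection pointwise confidence
    intervals, AICc/BIC model selection with frequentist model averaging over
    confounder subsets, reimplementations of rarefaction and
    scaling-with-ranked-subsampling baselines, Spearman residual-confounding
    assessment, and a synthetic-data generator emulating Poisson-MOI
    transduction, DNA-aliquot subsampling and read-depth saturation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    pracma,
    vegan,
    SummarizedExperiment,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Normalization, Regression, Sequencing, GeneTherapy
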