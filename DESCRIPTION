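Package: MultiDCoX
Title: Multi-Factor Analysis of Differential Co-Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Untargeted discovery of gene sets whose degree of co-expression
    differs across sample groups defined by multiple co-factors (genotypes,
    mutation status, clinical grade and the like). Co-expression of a gene
    set between two samples of the same stratum is summarised by the squared
    mean expression change, and a multi-factor linear model on these pairwise
    statistics quantifies each factor's influence on co-expression. A greedy
    set search (seed pairs, coefficient-optimising expansion, centroid-based
    augmentation and leave-one-out filtering) elicits differentially
    co-expressed gene sets de novo, gated post hoc by effect-size thresholds
    from the pooled coefficient distribution and a permutation criterion.
    Includes a seedable microarray-style expression simulator with planted
    differentially co-expressed sets and scoring utilities (FDR, FNR,
    failure and false-positive rates) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, DifferentialExpression, Network, Microarray
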