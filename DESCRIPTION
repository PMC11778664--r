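Package: hetloop
Title: Case/Control Genotype Biclustering for Genetic Heterogeneity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects genetically homogeneous subgroups (biclusters) within
    the case population of a case/control genotype study. Implements the
    iterative half-loop biclustering algorithm over allele-combination
    matrices with covariate-corrected differential-expression scores and a
    covariate-matched label-shuffled permutation null, together with the
    downstream stages that turn a discovered bicluster into reusable
    results: out-of-sample replication via projection onto the bicluster's
    dominant principal component with covariate-corrected AUCs,
    bicluster-informed polygenic risk scores with greedy LD clumping and
    p-value thresholding, liability-scale variance-explained conversion,
    and hypergeometric gene-set over-representation with permutation
    calibration. Includes a synthetic multi-arm genotype simulator with
    ancestry-covariate structure and planted biclusters for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: SNP, Clustering, GenomeWideAssociation, StatisticalMethod
RoxygenNote: 7.3.3
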