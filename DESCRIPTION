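Package: mcaoMeta
Title: Cross-Study Meta-Analysis of Brain-Ischemia Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-study meta-analysis of rodent brain-ischemia
    (middle cerebral artery occlusion versus sham) expression microarray
    data. Implements preprocessing (quantile normalization, k-nearest
    neighbour imputation, probe-to-gene collapse, per-gene
    standardization, common-gene intersection), five meta-analytic
    statistics (Fisher sum of logs, weighted Stouffer Z, fixed- and
    random-effects combination of Hedges' g with optional moderated
    variances, and the RankProduct permutation statistic) combined by
    vote counting, per-study differential expression with cross-study
    consensus, integration of meta and per-study calls, cross-species
    symbol intersection, hypergeometric gene-set enrichment against GMT
    collections, and protein-interaction subnetwork extraction. A
    synthetic multi-study data generator with known ground truth makes
    the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
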