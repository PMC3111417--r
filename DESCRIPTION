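Package: intromiR
Title: Intronic microRNA Target Prediction from Host Gene Expression
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts mRNA targets of intronic microRNAs from ordinary gene
    expression compendia, using the expression profile of each miRNA's host
    gene as a surrogate for the (unmeasured) miRNA. For every putative target
    a multi-regulator linear model is fitted per dataset by ordinary least
    squares (with non-negative and correlation-based variants), regression
    weights are L1-rescaled and pooled across datasets, and each host-target
    pair is scored against an empirical permutation null with a two-sided
    Wilcoxon-Mann-Whitney rank-sum statistic. Significant repressive
    interactions are called at an ROC-calibrated or fixed P-value cutoff, and
    host genes are classified as good or bad expression surrogates for their
    intronic miRNAs from the sign balance of their significant interactions.
    Includes a synthetic-compendium generator with planted regulatory edges
    and host-surrogacy scenarios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Regression, NetworkInference, Transcriptomics
RoxygenNote: 7.3.3
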