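Package: cser
Title: Gene Regulatory Network Inference from Causal Strength and Ensemble Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, directed gene regulatory networks from expression
    matrices. A complete gene graph is pruned with mutual information and
    first-order conditional mutual inclusive information (CMI2), a causal-
    strength score built from Kullback-Leibler divergences to intervention
    distributions; directed activation/repression edges among the surviving
    genes are then estimated with an ensemble of bagged Lasso regressions over
    linear and pairwise-product features. Includes WGCNA-style coexpression
    hub-gene preselection, a Wilcoxon/FDR differential-expression screen,
    sign-accuracy evaluation against signed gold standards, out-degree and
    maximal-clique-centrality node rankings, a Spearman correlation-network
    utility, and a synthetic benchmark generator producing signed DAG gold
    standards with matching expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
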