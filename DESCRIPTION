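Package: nextgene
Title: Literature-Guided Recommendation of Genes for the Next Experiment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds next-experiment gene recommendations from the order in
    which experiments are described in research articles. Detects
    gene/method mention candidates in sentences with dictionary matching,
    assembles consecutive-experiment gene pairs per article, encodes
    ordered gene pairs with heterogeneous categorical, numerical and
    embedding features, trains binary ranking classifiers with negative
    sampling, and evaluates whole-genome rankings with AUROC@k alongside
    network-proximity comparators (random walk with restart) and
    permutation-sampling Shapley attributions. Ships a synthetic-world
    generator with planted functional modules so the full pipeline runs
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    glmnet,
    ranger,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
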