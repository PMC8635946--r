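Package: dtifusion
Title: Drug-Target Interaction Prediction by Weighted Fusion of Multisource Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions in the positive-unlabeled setting by
    screening unlabeled pairs with three independent scorers (drug-similarity
    propagation, random walk with restart on the drug-target heterogeneous network,
    and WNN-GIP Kronecker regularized least squares), fusing the three revised
    score matrices by performance-weighted averaging, revising the training
    interaction matrix with the top-scoring unlabeled pairs, and training a
    bipartite local model with neighbor-based interaction-profile inferring
    (BLM-NII) on the revised matrix. Includes readers and writers for
    Yamanishi-style labeled matrix files, a seeded synthetic-data generator with
    planted hidden interactions for benchmarking, a pair-wise cross-validation
    harness with AUC/AUPR and top-fraction confusion metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
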