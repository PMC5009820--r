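Package: mutclust
Title: Somatic Mutation Burden Subtyping by Consensus Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a non-negative gene-by-patient mutation burden matrix from
    filtered somatic variants annotated with CADD deleteriousness scores,
    clusters patients by Kullback-Leibler non-negative matrix factorization
    with consensus-matrix and silhouette-based model selection, characterizes
    the resulting clusters by clinical stage enrichment (exact contingency
    tests) and differentially mutated genes (Wilcoxon rank-sum with
    Benjamini-Hochberg false discovery control), and evaluates a cluster
    prediction model with stratified cross-validation, per-fold information
    gain feature selection, and a label-shuffling permutation test. Includes a
    synthetic cohort generator with planted cluster structure so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    cluster,
    mclust,
    pROC
Config/testthat/edition: 3
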