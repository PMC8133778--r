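Package: pagstates
Title: Approach-Avoidance State Analysis for dPAG Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for miniscope calcium-imaging recordings of the
    dorsal periaqueductal gray (dPAG) during elevated-plus-maze and predator
    (rat) exposure assays. Provides trace conditioning (PCA artifact
    suppression, variance thresholding, z-scoring), pose-based behavior
    classification (freezing, approach, escape, head dips, rat movements),
    open/closed arm ensemble categorization with ROC-based preference scores,
    linear SVM decoding of arm type with permutation significance, a
    raised-cosine-basis encoding GLM, cross-assay Constrained Correlation
    Analysis (CoCA), and unsupervised avoidance/approach state discovery by
    k-means with AIC model selection and a Gaussian hidden Markov model. A
    synthetic-session generator with planted ground truth makes every stage
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
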