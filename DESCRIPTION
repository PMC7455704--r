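Package: divergescan
Title: Clustering-Free Differential Expression from Cell Density Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts differentially expressed genes in single-cell and
    spatial transcriptomics data without clustering cells. Each gene is
    scored by the Kullback-Leibler divergence between the kernel density,
    over a set of grid points in an input space (principal components,
    t-SNE/UMAP, or physical spatial coordinates), of the cells in which the
    gene is detected and a reference density of all cells. Significance is
    calibrated by randomization: the mean and standard deviation of the log
    divergence under random shuffling of detection labels are modeled as
    B-spline functions of the detection count. Includes a detection-weighted
    ("advanced") mode, gene clustering by expression-distribution profile, a
    negative-binomial cluster/path benchmark simulator with ground-truth
    labels, and ROC AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
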