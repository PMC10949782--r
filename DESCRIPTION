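Package: scbench
Title: Benchmarking Framework and Reference Models for Single-Cell Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for single-cell transcriptomics with a
    uniform fit-predict-score contract across four tasks: clustering (zero-inflated
    negative binomial autoencoder with deep embedded clustering, its pairwise
    constrained variant, and a graph autoencoder on the cell-gene bipartite graph),
    supervised cell-type annotation (multinomial logistic regression, multilayer
    perceptron, and a transductive graph neural network), dropout imputation
    (parallel block multilayer perceptrons and a graph autoencoder, benchmarked by
    simulated masking), and spatial cell-type deconvolution (signature-based
    non-negative least squares and seeded non-negative matrix factorization).
    Includes a dataset container with Matrix Market and CSV readers, composable
    serializable preprocessing pipelines, weighted graph construction and
    propagation primitives, task-aligned metrics, a seeded synthetic-data
    generator so every task is testable offline, and a benchmark harness with
    grid search, multi-seed averaging, and single-command-line reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    withr,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
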