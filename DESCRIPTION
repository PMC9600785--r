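Package: cdgraph
Title: Bayesian Network Structure Learning with Causal Direction Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Score-based structure learning for Bayesian networks such as
    protein signaling networks. Pairwise causal directions are estimated
    first with an information-geometric (IGCI) spacing estimator and stored
    in a direction matrix; the weighted adjacency matrix is then obtained by
    minimising a structural-equation least-squares loss under a
    trace-exponential acyclicity constraint and the direction-matrix
    constraint via Lagrange multipliers and gradient descent; finally weak
    edges are pruned by second-order polynomial regression on each node's
    parents. Includes a quadratic structural-equation-model data generator,
    structural Hamming distance and binary-classification evaluation, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
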