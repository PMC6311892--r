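Package: dwnnrls
Title: Kronecker Kernel Regularized Least Squares for Bipartite Association Prediction
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts missing links in a bipartite association network (for
    example circRNA-disease associations) with regularized least squares over
    the Kronecker product of per-side kernels. Similarities are Gaussian
    interaction profile (GIP) kernels computed from the binary association
    matrix, optionally integrated with an ontology-DAG semantic similarity on
    the column side. Cold-start entities (rows or columns with no known
    associations) receive initial scores from a decreasing-weight k-nearest
    neighbour average. Includes a cross-validation/AUC evaluation harness, six
    baseline predictors (RLS-avg, RLS-Kron, NetLapRLS, KATZ, NBI, WP), a
    synthetic block-model generator with a correlated random DAG, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
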