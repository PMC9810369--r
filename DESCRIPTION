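Package: hypercon
Title: Hyperbolic Disc Embedding and Anomaly Detection for Functional
    Connectivity Networks
Version: 0.1.0
Authors@R:
    person("hypercon", "developers", email = "hypercon@example.org",
           role = c("aut", "cre"))
Description: Builds binary functional-connectivity graphs from node-by-time
    series matrices by absolute-value correlation thresholding with a
    scale-free plus largest-component retention window, benchmarks graph
    embeddings in constant-curvature spaces (Euclidean, hyperbolic,
    spherical) by Riemannian stochastic gradient descent with distortion and
    mean-average-precision fidelity scores, re-implements maximum-likelihood
    S1/H2 hyperbolic-disc embedding (hidden degrees, inverse temperature,
    angular coordinates), quantifies embedding reproducibility by the
    coefficient of variation of a distance analog over repeated embeddings,
    and flags an individual's anomalous edges against a control cohort's
    per-edge distance (or correlation) distributions. Includes a synthetic
    data generator (block-correlated multivariate normal series and S1
    geometric networks with known ground truth) used throughout the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
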