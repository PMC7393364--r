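Package: explspace
Title: Latent Subtype Discovery by Clustering in Explanation Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a binary diagnostic classifier (a bagged ensemble of
    CART-style decision trees), computes exact instance-wise Shapley
    attributions of its predicted probability with the path-dependent
    tree algorithm, and treats the resulting attribution matrix -- the
    "explanation space" -- as a new feature space for cluster analysis.
    Includes a hypercube-cluster synthetic benchmark generator,
    dimensionality-reduction adapters (PCA, Isomap, t-SNE), Ward
    agglomerative clustering, from-scratch cluster validity indices
    (Davies-Bouldin, Calinski-Harabasz, Silhouette) and exact adjusted
    mutual information, plus an end-to-end benchmark protocol comparing
    subtype recovery in explanation space against raw feature space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
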