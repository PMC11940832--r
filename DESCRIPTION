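Package: kareaclust
Title: Convex-Hull Area Minimizing Divisive Clustering for 2D Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Greedy divisive clustering of 2D point sets (typically PCA
    embeddings of single-cell RNA-seq expression matrices) that minimizes
    the total convex-hull area of the clusters. Each round bisects one
    cluster along a line through two of its hull vertices, choosing the
    split that removes the most area, and records the divisive history as
    a binary cluster tree. Includes an area-ratio rule for choosing the
    number of clusters, K-center (farthest-first traversal), K-median
    (Lloyd iterations with geometric-median centers) and K-means (Lloyd)
    baselines, normalized mutual information evaluation, CSV and
    MatrixMarket readers with a PCA front end, a synthetic fixture
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
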