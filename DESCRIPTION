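Package: kliclust
Title: Kernel Learning Integrative Clustering and Cluster-Of-Clusters Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative clustering of multiple datasets that share the same
    observations, such as multi-omic studies measuring one set of samples on
    several platforms. Consensus matrices obtained by resampled consensus
    clustering of each dataset are positive semi-definite and can therefore be
    treated as kernels; the package combines them by localized multiple-kernel
    k-means with per-observation, per-dataset weights obtained by convex
    quadratic programming (KLIC). The unweighted Cluster-Of-Clusters Analysis
    (COCA), which stacks per-dataset cluster indicator matrices and applies
    consensus clustering to the result, is provided for comparison, together
    with synthetic-data generators, adjusted Rand index and silhouette
    evaluation, and CSV input/output for matrices and labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
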