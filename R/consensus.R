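# Resampled consensus clustering of a single dataset: co-clustering matrices,
# the consensus matrix, and the proportion-of-ambiguous-entries choice of K.

#' Co-clustering (connectivity) matrix of one clustering run
#'
#' Entry (i, j) is 1 when items i and j were both present in the run and were
#' assigned to the same cluster, and 0 otherwise. Items excluded from the run
#' are encoded as `NA` labels; their rows and columns (including the diagonal)
#' are zero.
#'
#' @param labels Integer vector of cluster labels, with `NA` marking items not
#'   present in this run.
#' @param n_items Expected number of items; defaults to `length(labels)` and
#'   is checked against it.
#' @return An `n_items` x `n_items` 0/1 matrix, symmetric, with diagonal 1 for
#'   included items. Invariant to relabelling of clusters.
#' @examples
#' coclustering_matrix(c(1, 1, 2))
#' coclustering_matrix(c(1, 1, NA))  # third item excluded from the run
#' @export
coclustering_matrix <- function(labels, n_items = length(labels)) {
  if (length(labels) != n_items) {
    input_error(sprintf("labels has length %d but n_items = %d",
                        length(labels), n_items))
  }
  included <- !is.na(labels)
  cc <- outer(labels, labels, `==`)
  cc[!is.finite(cc) | is.na(cc)] <- FALSE
  cc <- cc * 1
  diag(cc) <- as.numeric(included)
  dimnames(cc) <- list(names(labels), names(labels))
  cc
}

#' Draw the item/feature subsample for one resampling run
#'
#' Without-replacement samples of `ceiling(item_proportion * n_items)` items
#' and `ceiling(feature_proportion * n_features)` features, deterministic
#' given `(seed, run_index)`.
#'
#' @param n_items,n_features Dimensions of the dataset being resampled.
#' @param item_proportion,feature_proportion Proportions in (0, 1].
#' @param seed Base seed of the resampling scheme.
#' @param run_index Index h of the run (1-based).
#' @return List with sorted integer vectors `items` and `features`.
#' @export
subsample <- function(n_items, n_features, item_proportion = 0.8,
                      feature_proportion = 1, seed = NULL, run_index = 1) {
  if (item_proportion <= 0 || item_proportion > 1 ||
      feature_proportion <= 0 || feature_proportion > 1) {
    config_error("item_proportion and feature_proportion must be in (0, 1]")
  }
  n_i <- ceiling(item_proportion * n_items)
  n_f <- ceiling(feature_proportion * n_features)
  if (n_i < 2) config_error("item subsample would contain fewer than 2 items")
  if (n_f < 1) config_error("feature subsample would be empty")
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, 7L, run_index), {
    list(items = sort(sample.int(n_items, n_i)),
         features = sort(sample.int(n_features, n_f)))
  })
}

# Shared finaliser: entrywise ratio of co-clustering counts to co-sampling
# counts, with max(1, .) guarding pairs that were never co-sampled (their
# consensus entry is 0).
finalize_consensus <- function(sum_cc, copair, n_runs, K = NA_integer_) {
  values <- sum_cc / pmax(1, copair)
  structure(values,
            copair_counts = copair,
            n_runs = n_runs,
            K = K,
            class = c("consensus_matrix", class(values)))
}

#' Consensus matrix from a set of co-clustering runs
#'
#' Entry (i, j) is the number of runs in which i and j were co-clustered,
#' divided by the number of runs in which both were sampled; pairs that were
#' never co-sampled get 0. The co-sampling counts are kept as the
#' `copair_counts` attribute.
#'
#' @param coclusters List of N x N co-clustering matrices (one per run).
#' @param included List of length-N logical vectors marking which items were
#'   present in each run. Defaults to the diagonal of each co-clustering
#'   matrix.
#' @return N x N consensus matrix (class `consensus_matrix`), symmetric with
#'   entries in \[0, 1\] and diagonal 1 for every item sampled at least once.
#' @export
consensus_matrix <- function(coclusters, included = NULL) {
  if (length(coclusters) < 1) input_error("need at least one co-clustering run")
  n <- nrow(coclusters[[1]])
  if (any(!vapply(coclusters, function(m) is.matrix(m) && all(dim(m) == n), TRUE))) {
    input_error("all co-clustering matrices must be square with the same N")
  }
  if (is.null(included)) {
    included <- lapply(coclusters, function(m) diag(m) > 0)
  }
  if (length(included) != length(coclusters) ||
      any(lengths(included) != n)) {
    input_error("included must hold one length-N logical vector per run")
  }
  sum_cc <- Reduce(`+`, coclusters)
  copair <- Reduce(`+`, lapply(included, function(v) tcrossprod(as.numeric(v))))
  out <- finalize_consensus(sum_cc, copair, length(coclusters))
  dimnames(out) <- dimnames(coclusters[[1]])
  out
}

#' Cluster a single dataset once
#'
#' Base clusterer used inside the resampling loop and for the per-dataset step
#' of COCA. k-means (Euclidean, restarted) is the default; PAM and hierarchical
#' clustering with average or complete linkage are available, each with
#' Euclidean or correlation (1 - Pearson) distances.
#'
#' @param data Numeric observations x features matrix.
#' @param K Number of clusters (2 <= K <= N; K = 1 returns a single cluster).
#' @param method One of "kmeans", "pam", "hier_average", "hier_complete".
#' @param distance "euclidean" or "correlation"; k-means supports only
#'   Euclidean.
#' @param seed Seed for the stochastic methods (k-means restarts).
#' @param n_restarts,max_iter k-means restart count and iteration cap.
#' @return Integer labels in 1..K, named by the row names of `data`.
#' @export
cluster_data <- function(data, K,
                         method = c("kmeans", "pam", "hier_average", "hier_complete"),
                         distance = c("euclidean", "correlation"),
                         seed = NULL, n_restarts = 10, max_iter = 300) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  data <- as.matrix(data)
  n <- nrow(data)
  if (K > n) input_error(sprintf("K = %d exceeds N = %d", K, n))
  if (K < 1) input_error("K must be >= 1")
  labels <- if (method == "kmeans") {
    if (distance != "euclidean") {
      input_error("k-means supports only Euclidean distance")
    }
    kmeans_restart(data, K, n_restarts = n_restarts, max_iter = max_iter,
                   seed = seed)
  } else {
    d <- if (distance == "euclidean") stats::dist(data) else
      stats::as.dist(1 - stats::cor(t(data)))
    if (method == "pam") {
      as.integer(cluster::pam(d, k = K, diss = TRUE, cluster.only = TRUE))
    } else {
      linkage <- if (method == "hier_average") "average" else "complete"
      as.integer(stats::cutree(stats::hclust(d, method = linkage), k = K))
    }
  }
  names(labels) <- rownames(data)
  labels
}

#' Resampled consensus clustering of one dataset
#'
#' Repeatedly subsamples the observations (and optionally the features),
#' clusters each subsample into K groups, and aggregates the co-clustering
#' matrices into a consensus matrix. With a stable clustering structure the
#' consensus entries concentrate near 0 and 1.
#'
#' @inheritParams cluster_data
#' @param n_runs Number of resampling runs H (default 1000).
#' @param item_proportion,feature_proportion Subsampling proportions; the
#'   defaults (80% of observations, all features) are the usual consensus
#'   clustering choice.
#' @param clusterer Optional `function(data, K, seed)` returning integer
#'   labels; overrides `method`. This is the plug-in point for external base
#'   clusterers (sparse k-means, Bayesian hierarchical clustering, ...).
#' @param seed Base seed; the full resampling trajectory is deterministic
#'   given it.
#' @return N x N `consensus_matrix` (see [consensus_matrix()]), with row and
#'   column names taken from `data`.
#' @examples
#' sim <- generate_dataset(separability = 5, n_per_cluster = 10, seed = 1)
#' cm <- consensus_cluster(sim$data, K = 6, n_runs = 20, seed = 1)
#' range(cm)
#' @export
consensus_cluster <- function(data, K, n_runs = 1000, item_proportion = 0.8,
                              feature_proportion = 1,
                              method = "kmeans", clusterer = NULL,
                              seed = NULL, n_restarts = 10) {
  data <- as.matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  if (K < 2) input_error("consensus clustering needs K >= 2")
  if (n_runs < 1) config_error("n_runs must be >= 1")
  if (is.null(clusterer)) {
    clusterer <- function(x, k, seed) {
      cluster_data(x, k, method = method, seed = seed, n_restarts = n_restarts)
    }
  }
  sum_cc <- matrix(0, n, n)
  copair <- matrix(0, n, n)
  for (h in seq_len(n_runs)) {
    sub <- subsample(n, p, item_proportion, feature_proportion,
                     seed = seed, run_index = h)
    run_labels <- tryCatch(
      clusterer(data[sub$items, sub$features, drop = FALSE], K,
                if (is.null(seed)) NULL else derive_seed(seed, 13L, h)),
      error = function(e) {
        numeric_error(sprintf("base clusterer failed on run %d (K = %d): %s",
                              h, K, conditionMessage(e)))
      }
    )
    full <- rep(NA_integer_, n)
    full[sub$items] <- as.integer(run_labels)
    sum_cc <- sum_cc + coclustering_matrix(full, n)
    inc <- numeric(n)
    inc[sub$items] <- 1
    copair <- copair + tcrossprod(inc)
  }
  out <- finalize_consensus(sum_cc, copair, n_runs, K = as.integer(K))
  dimnames(out) <- list(rownames(data), rownames(data))
  out
}

#' Choose K by the proportion of ambiguous consensus entries
#'
#' Among candidate numbers of clusters, picks the one whose consensus matrix
#' has the smallest proportion of off-diagonal entries strictly inside the
#' ambiguity band (entries near 0 or 1 indicate pairs that are consistently
#' split or consistently joined). Ties go to the smallest K.
#'
#' @param consensus_by_k Named list of consensus matrices; names are the
#'   candidate K values.
#' @param ambiguity_band Length-2 numeric `(lo, hi)`; entries strictly inside
#'   count as ambiguous. Default `c(0.1, 0.9)`.
#' @return The selected K (integer).
#' @export
select_k_monti <- function(consensus_by_k, ambiguity_band = c(0.1, 0.9)) {
  if (length(consensus_by_k) < 1) input_error("consensus_by_k is empty")
  ks <- as.integer(names(consensus_by_k))
  if (anyNA(ks)) input_error("consensus_by_k must be named by integer K values")
  prop <- vapply(consensus_by_k, function(m) {
    off <- m[row(m) != col(m)]
    mean(off > ambiguity_band[1] & off < ambiguity_band[2])
  }, numeric(1))
  ord <- order(ks)
  ks <- ks[ord]
  prop <- prop[ord]
  ks[which.min(prop)]
}
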