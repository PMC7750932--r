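# Synthetic benchmark generators: Gaussian clusters with controllable
# separability, used throughout the test suite and the simulation studies.

#' Generate one Gaussian-cluster benchmark dataset
#'
#' Draws `n_clusters` equally sized clusters in `n_relevant + n_noise`
#' dimensions. An observation in cluster k has mean `k * separability` in each
#' of the `n_relevant` signal variables and mean 0 in the `n_noise` irrelevant
#' variables; the covariance is the identity. Larger `separability` therefore
#' gives a cleaner clustering structure, `separability = 0` gives pure noise.
#'
#' @param separability Non-negative scale `s` of the cluster means (cluster k
#'   is centred at `k * s` in every signal variable).
#' @param n_clusters Number of clusters (default 6).
#' @param n_per_cluster Observations per cluster (default 50, i.e. N = 300).
#' @param n_relevant Number of variables carrying the cluster signal
#'   (default 2).
#' @param n_noise Number of additional N(0, 1) variables with no clustering
#'   structure (default 0; use 13 for the irrelevant-variable setting).
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#'
#' @return A list with elements `data` (an N x P numeric matrix with
#'   observation IDs as row names) and `labels` (named integer vector of true
#'   cluster labels in 1..`n_clusters`).
#' @examples
#' sim <- generate_dataset(separability = 2, seed = 1)
#' dim(sim$data)
#' table(sim$labels)
#' @export
generate_dataset <- function(separability, n_clusters = 6, n_per_cluster = 50,
                             n_relevant = 2, n_noise = 0, seed = NULL) {
  if (separability < 0) config_error("separability must be >= 0")
  if (n_clusters < 1 || n_per_cluster < 1 || n_relevant < 1 || n_noise < 0) {
    config_error("n_clusters, n_per_cluster and n_relevant must be positive; n_noise >= 0")
  }
  n <- n_clusters * n_per_cluster
  p <- n_relevant + n_noise
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  values <- with_seed(seed, matrix(stats::rnorm(n * p), nrow = n, ncol = p))
  values[, seq_len(n_relevant)] <- values[, seq_len(n_relevant)] +
    labels * separability
  ids <- sprintf("obs_%03d", seq_len(n))
  rownames(values) <- ids
  colnames(values) <- c(sprintf("signal_%d", seq_len(n_relevant)),
                        if (n_noise > 0) sprintf("noise_%d", seq_len(n_noise)))
  names(labels) <- ids
  list(data = values, labels = as.integer(labels) |> stats::setNames(ids))
}

#' Generate a collection of similar datasets sharing one partition
#'
#' All `n_datasets` draws use the same true labels and the same separability;
#' only the Gaussian noise differs (independent draws from derived seeds).
#' This emulates several equally informative data views of one set of samples.
#'
#' @inheritParams generate_dataset
#' @param n_datasets Number of datasets M (>= 2).
#' @return A named list (`A`, `B`, ...) of `generate_dataset()` results; all
#'   elements carry identical `labels`.
#' @export
generate_similar_collection <- function(n_datasets, separability, n_clusters = 6,
                                        n_per_cluster = 50, n_relevant = 2,
                                        n_noise = 0, seed = NULL) {
  if (n_datasets < 2) config_error("n_datasets must be >= 2")
  out <- lapply(seq_len(n_datasets), function(m) {
    generate_dataset(separability, n_clusters, n_per_cluster, n_relevant,
                     n_noise, seed = if (is.null(seed)) NULL else derive_seed(seed, 101L, m))
  })
  names(out) <- if (n_datasets <= 26) LETTERS[seq_len(n_datasets)] else
    sprintf("dataset_%d", seq_len(n_datasets))
  out
}

#' Generate datasets with the same partition but different separabilities
#'
#' One dataset per entry of `s_levels`, all sharing the same true labels.
#' Emulates combining informative and noisy data views: low `s` datasets carry
#' little or no information about the common clustering structure.
#'
#' @inheritParams generate_dataset
#' @param s_levels Numeric vector (length >= 1) of separability levels; the
#'   output preserves this order and is named by the levels.
#' @return A named list of `generate_dataset()` results with shared `labels`.
#' @export
generate_heterogeneous_collection <- function(s_levels, n_clusters = 6,
                                              n_per_cluster = 50, n_relevant = 2,
                                              n_noise = 0, seed = NULL) {
  if (length(s_levels) < 1) config_error("s_levels must be non-empty")
  out <- lapply(seq_along(s_levels), function(m) {
    generate_dataset(s_levels[m], n_clusters, n_per_cluster, n_relevant,
                     n_noise, seed = if (is.null(seed)) NULL else derive_seed(seed, 103L, m))
  })
  names(out) <- make.unique(as.character(s_levels))
  out
}
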