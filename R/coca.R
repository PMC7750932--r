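# Cluster-Of-Clusters Analysis: stack per-dataset cluster indicators into a
# matrix of clusters, run consensus clustering on its columns, and extract the
# final partition by average-linkage hierarchical clustering.

#' Build the matrix of clusters (MOC)
#'
#' Stacks the one-hot cluster-membership indicators of every dataset into a
#' single binary matrix with one row per (dataset, cluster) pair and one
#' column per observation. Observations missing from a dataset get all-zero
#' entries in that dataset's rows.
#'
#' @param partitions List (one element per dataset, optionally named) of
#'   integer label vectors. Labels must be named by observation ID when the
#'   datasets cover different observations; `NA` labels mark missing
#'   observations.
#' @param obs_ids Character vector fixing the observation universe and column
#'   order. Defaults to the union of the partition names in order of first
#'   appearance (or positional IDs when all partitions are unnamed and of
#'   equal length).
#' @return Binary matrix with `sum(K_m)` rows and `length(obs_ids)` columns;
#'   row names are `<dataset>.<cluster>` and the `row_info` attribute holds a
#'   data frame mapping rows to datasets and cluster labels.
#' @examples
#' build_moc(list(d1 = c(a = 1, b = 1, c = 2), d2 = c(a = 1, b = 2, c = 2)))
#' @export
build_moc <- function(partitions, obs_ids = NULL) {
  if (length(partitions) < 1) input_error("need at least one partition")
  named <- vapply(partitions, function(p) !is.null(names(p)), TRUE)
  if (is.null(obs_ids)) {
    if (all(named)) {
      obs_ids <- unique(unlist(lapply(partitions, names)))
    } else if (length(unique(lengths(partitions))) == 1) {
      obs_ids <- sprintf("obs_%03d", seq_len(length(partitions[[1]])))
      partitions <- lapply(partitions, stats::setNames, obs_ids)
    } else {
      alignment_error("unnamed partitions of different lengths cannot be aligned")
    }
  } else {
    partitions <- lapply(partitions, function(p) {
      if (is.null(names(p))) {
        if (length(p) != length(obs_ids)) {
          alignment_error("unnamed partition length does not match obs_ids")
        }
        names(p) <- obs_ids
      }
      p
    })
  }
  ds_names <- names(partitions) %||% sprintf("dataset_%d", seq_along(partitions))
  ds_names[ds_names == ""] <- sprintf("dataset_%d", which(ds_names == ""))
  blocks <- vector("list", length(partitions))
  info <- vector("list", length(partitions))
  for (m in seq_along(partitions)) {
    p <- partitions[[m]]
    unknown <- setdiff(names(p), obs_ids)
    if (length(unknown) > 0) {
      alignment_error(sprintf("partition '%s' has observations outside the universe: %s",
                              ds_names[m], paste(utils::head(unknown, 3), collapse = ", ")))
    }
    aligned <- p[match(obs_ids, names(p))]  # NA where the observation is absent
    ks <- sort(unique(aligned[!is.na(aligned)]))
    block <- matrix(0, nrow = length(ks), ncol = length(obs_ids),
                    dimnames = list(sprintf("%s.%s", ds_names[m], ks), obs_ids))
    for (j in seq_along(ks)) {
      block[j, which(aligned == ks[j])] <- 1
    }
    blocks[[m]] <- block
    info[[m]] <- data.frame(dataset = ds_names[m], cluster = ks,
                            stringsAsFactors = FALSE)
  }
  moc <- do.call(rbind, blocks)
  attr(moc, "row_info") <- do.call(rbind, info)
  moc
}

#' Consensus clustering of the MOC and final partition extraction
#'
#' Runs resampled consensus clustering over the observations (the columns of
#' the MOC, treated as binary feature vectors), then extracts the final
#' partition by average-linkage hierarchical clustering on the dissimilarity
#' `1 - consensus`, cut at K.
#'
#' @param moc Binary matrix from [build_moc()].
#' @param K Global number of clusters (2 <= K <= N).
#' @param n_runs,item_proportion Resampling scheme for the consensus step
#'   (observations are resampled; all MOC rows are always kept).
#' @param inner_method Base clusterer for the consensus runs (default
#'   k-means on the binary columns, Euclidean distance).
#' @param seed Base seed.
#' @param n_restarts k-means restarts per run.
#' @return List with `labels` (named integer vector) and `consensus`
#'   (N x N `consensus_matrix` of the MOC columns).
#' @export
coca_cluster <- function(moc, K, n_runs = 1000, item_proportion = 0.8,
                         inner_method = "kmeans", seed = NULL, n_restarts = 10) {
  moc <- as.matrix(moc)
  n <- ncol(moc)
  if (K < 2) input_error("COCA needs K >= 2")
  if (K > n) input_error(sprintf("K = %d exceeds N = %d", K, n))
  cm <- consensus_cluster(t(moc), K, n_runs = n_runs,
                          item_proportion = item_proportion,
                          feature_proportion = 1,
                          method = inner_method, seed = seed,
                          n_restarts = n_restarts)
  labels <- moc_consensus_to_labels(cm, K)
  list(labels = labels, consensus = cm)
}

# Average-linkage hierarchical clustering on 1 - consensus, cut at K.
moc_consensus_to_labels <- function(consensus, K) {
  d <- stats::as.dist(1 - consensus)
  labels <- stats::cutree(stats::hclust(d, method = "average"), k = K)
  names(labels) <- rownames(consensus)
  as.integer(labels) |> stats::setNames(rownames(consensus))
}

#' Choose K by maximum average silhouette width
#'
#' Scores each candidate partition by its average silhouette width under the
#' supplied distance matrix and returns the K with the largest average.
#' Singleton clusters score 0; ties go to the smallest K.
#'
#' @param labels_by_k Named list of integer label vectors; names are the
#'   candidate K values.
#' @param distance N x N symmetric distance matrix with zero diagonal.
#' @return The selected K (integer), with the per-candidate averages attached
#'   as the `silhouette_by_k` attribute.
#' @export
select_k_silhouette <- function(labels_by_k, distance) {
  if (length(labels_by_k) < 1) input_error("labels_by_k is empty")
  ks <- as.integer(names(labels_by_k))
  if (anyNA(ks)) input_error("labels_by_k must be named by integer K values")
  ord <- order(ks)
  ks <- ks[ord]
  avg <- vapply(labels_by_k[ord], function(l) {
    silhouette_widths(l, distance)$average
  }, numeric(1))
  structure(ks[which.max(avg)],
            silhouette_by_k = stats::setNames(avg, ks))
}

#' Full COCA pipeline on a list of datasets
#'
#' Clusters each dataset separately, stacks the resulting partitions into the
#' MOC, runs consensus clustering on it, and extracts the final partition. If
#' `k_range` is supplied instead of `K`, every candidate is run and the one
#' maximizing the average silhouette (under distance `1 - consensus`) is
#' returned.
#'
#' @param datasets List of numeric matrices (observations x features) with
#'   observation IDs as row names; datasets may cover different observation
#'   subsets.
#' @param k_per_dataset Integer vector of per-dataset cluster counts K_m
#'   (recycled if length 1).
#' @param K Global number of clusters; alternatively give `k_range`.
#' @param k_range Integer vector of candidate K values (e.g. `2:10`).
#' @param n_runs,item_proportion Resampling scheme for the MOC consensus step.
#' @param method Base clusterer for the per-dataset step (see
#'   [cluster_data()]).
#' @param seed Base seed.
#' @return List with `labels`, `k_selected`, `silhouette_by_k`, `consensus`,
#'   `moc` and `partitions` (the per-dataset label vectors).
#' @examples
#' sets <- generate_similar_collection(2, separability = 3,
#'                                     n_per_cluster = 10, seed = 1)
#' fit <- run_coca(lapply(sets, `[[`, "data"), k_per_dataset = 6, K = 6,
#'                 n_runs = 20, seed = 1)
#' table(fit$labels, sets$A$labels)
#' @export
run_coca <- function(datasets, k_per_dataset, K = NULL, k_range = NULL,
                     n_runs = 1000, item_proportion = 0.8, method = "kmeans",
                     seed = NULL) {
  if (is.null(K) && is.null(k_range)) input_error("give either K or k_range")
  k_per_dataset <- rep_len(as.integer(k_per_dataset), length(datasets))
  partitions <- lapply(seq_along(datasets), function(m) {
    cluster_data(datasets[[m]], k_per_dataset[m], method = method,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, 51L, m))
  })
  names(partitions) <- names(datasets)
  moc <- build_moc(partitions)
  candidates <- if (is.null(k_range)) K else sort(unique(as.integer(k_range)))
  fits <- lapply(seq_along(candidates), function(i) {
    coca_cluster(moc, candidates[i], n_runs = n_runs,
                 item_proportion = item_proportion,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, 53L, i))
  })
  if (length(candidates) == 1) {
    chosen <- 1L
    sil <- stats::setNames(NA_real_, candidates)
  } else {
    labels_by_k <- stats::setNames(lapply(fits, `[[`, "labels"), candidates)
    avg <- vapply(seq_along(fits), function(i) {
      silhouette_widths(fits[[i]]$labels, 1 - unclass(fits[[i]]$consensus))$average
    }, numeric(1))
    sil <- stats::setNames(avg, candidates)
    chosen <- which.max(avg)
  }
  list(labels = fits[[chosen]]$labels,
       k_selected = candidates[chosen],
       silhouette_by_k = sil,
       consensus = fits[[chosen]]$consensus,
       moc = moc,
       partitions = partitions)
}
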