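# The KLIC pipeline: per-dataset consensus matrices, PSD repair, localized
# multiple-kernel k-means, silhouette-based choice of the number of clusters,
# and missing-observation handling.

#' Distance induced by a kernel
#'
#' The feature-space distance `d_ij = sqrt(K_ii + K_jj - 2 K_ij)` (clamped at
#' zero before the square root), used to score partitions of kernel output by
#' their silhouette widths.
#'
#' @param kernel N x N PSD kernel matrix.
#' @return N x N symmetric distance matrix with zero diagonal.
#' @export
kernel_to_distance <- function(kernel) {
  check_square_symmetric(kernel, what = "kernel")
  d <- diag(unclass(kernel))
  d2 <- (outer(d, d, `+`) - 2 * unclass(kernel))
  d2[d2 < 0] <- 0
  out <- sqrt((d2 + t(d2)) / 2)
  diag(out) <- 0
  dimnames(out) <- dimnames(kernel)
  out
}

#' KLIC on precomputed kernel or similarity matrices
#'
#' Skips the consensus stage of [run_klic()]: any symmetric similarity
#' matrices are accepted, repaired to PSD by [spectral_shift()] if needed, and
#' combined by [localized_mkl_kmeans()]. When a range of K values is given,
#' the full optimisation is run for every candidate and the one maximizing
#' the average silhouette width (under each candidate's own combined-kernel
#' distance) is selected.
#'
#' @param kernels List of M symmetric N x N matrices (aligned on the same
#'   observations; row names, when present, must agree).
#' @param K Number of clusters; alternatively give `k_range`.
#' @param k_range Integer vector of candidate K values (e.g. `2:10`).
#' @param observed_mask N x M logical matrix; `FALSE` marks observations
#'   missing from a dataset, which receive weight zero there. Default: all
#'   observed.
#' @param tol,max_iter,n_restarts Passed to [localized_mkl_kmeans()].
#' @param seed Base seed (each candidate K gets a derived stream).
#' @return An object of class `klic_result`: list with `labels`, `weights`
#'   (N x M), `combined_kernel`, `k_selected`, `silhouette_by_k`,
#'   `objective_trace`, `n_iter`, `converged`, and `per_dataset_consensus`
#'   (NULL here; filled by [run_klic()]).
#' @export
run_klic_from_kernels <- function(kernels, K = NULL, k_range = NULL,
                                  observed_mask = NULL, tol = 1e-5,
                                  max_iter = 100, seed = NULL, n_restarts = 10) {
  if (is.null(K) && is.null(k_range)) input_error("give either K or k_range")
  if (length(kernels) < 1) input_error("need at least one kernel")
  for (k in kernels) check_square_symmetric(k, what = "kernel")
  ids <- Reduce(function(a, b) a %||% b, lapply(kernels, rownames))
  for (k in kernels) {
    if (!is.null(rownames(k)) && !is.null(ids) && !identical(rownames(k), ids)) {
      alignment_error("kernel row names do not agree across datasets")
    }
  }
  kernels <- lapply(kernels, spectral_shift)
  candidates <- if (is.null(k_range)) as.integer(K) else
    sort(unique(as.integer(k_range)))
  fits <- lapply(seq_along(candidates), function(i) {
    localized_mkl_kmeans(kernels, candidates[i], observed_mask = observed_mask,
                         tol = tol, max_iter = max_iter,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, 23L, candidates[i]),
                         n_restarts = n_restarts)
  })
  if (length(candidates) == 1) {
    chosen <- 1L
    sil <- stats::setNames(NA_real_, candidates)
  } else {
    avg <- vapply(seq_along(fits), function(i) {
      silhouette_widths(fits[[i]]$labels,
                        kernel_to_distance(fits[[i]]$combined_kernel))$average
    }, numeric(1))
    sil <- stats::setNames(avg, candidates)
    chosen <- which.max(avg)
  }
  fit <- fits[[chosen]]
  structure(list(labels = fit$labels,
                 weights = fit$weights,
                 combined_kernel = fit$combined_kernel,
                 k_selected = candidates[chosen],
                 silhouette_by_k = sil,
                 objective_trace = fit$objective_trace,
                 objective = fit$objective,
                 n_iter = fit$n_iter,
                 converged = fit$converged,
                 per_dataset_consensus = NULL),
            class = "klic_result")
}

#' Kernel learning integrative clustering of multiple datasets
#'
#' The full pipeline: resampled consensus clustering of each dataset yields a
#' consensus matrix per dataset; these are positive semi-definite (up to the
#' effect of item subsampling, repaired by [spectral_shift()]) and are treated
#' as kernels and combined by localized multiple-kernel k-means, giving a
#' global partition together with per-observation, per-dataset weights.
#' Observations missing from a dataset contribute zero rows/columns to its
#' consensus matrix and are forced to weight zero there; their weights are
#' spread over the datasets that do observe them.
#'
#' @param datasets List of M numeric matrices (observations x features) with
#'   observation IDs as row names; the union of IDs defines the observation
#'   universe and each observation must appear in at least one dataset.
#'   Unnamed matrices must all have the same number of rows and are aligned
#'   positionally.
#' @param K Global number of clusters; alternatively give `k_range`.
#' @param k_range Integer vector of candidate K values, scored by average
#'   silhouette width under each candidate's combined-kernel distance.
#' @param k_per_dataset Number of clusters used inside each dataset's
#'   consensus runs (recycled; defaults to `K`, or to the largest candidate
#'   in `k_range`).
#' @param n_runs,item_proportion,feature_proportion Resampling scheme of the
#'   consensus stage (defaults: 1000 runs, 80% of observations, all
#'   features).
#' @param method Base clusterer (see [cluster_data()]).
#' @param clusterers Optional list of M functions `(data, K, seed) -> labels`
#'   overriding `method` per dataset.
#' @param tol,max_iter,n_restarts Passed to [localized_mkl_kmeans()].
#' @param seed Base seed; every stochastic sub-step derives its own stream.
#' @return A `klic_result` (see [run_klic_from_kernels()]) whose
#'   `per_dataset_consensus` holds the M repaired N x N consensus matrices.
#' @examples
#' sets <- generate_similar_collection(2, separability = 3,
#'                                     n_per_cluster = 10, seed = 1)
#' res <- run_klic(lapply(sets, `[[`, "data"), K = 6, n_runs = 20, seed = 1)
#' res
#' @export
run_klic <- function(datasets, K = NULL, k_range = NULL, k_per_dataset = NULL,
                     n_runs = 1000, item_proportion = 0.8,
                     feature_proportion = 1, method = "kmeans",
                     clusterers = NULL, tol = 1e-5, max_iter = 100,
                     seed = NULL, n_restarts = 10) {
  if (is.null(K) && is.null(k_range)) input_error("give either K or k_range")
  if (length(datasets) < 1) input_error("need at least one dataset")
  datasets <- lapply(datasets, as.matrix)
  named <- vapply(datasets, function(d) !is.null(rownames(d)), TRUE)
  if (!all(named)) {
    if (length(unique(vapply(datasets, nrow, 1L))) != 1) {
      alignment_error("unnamed datasets of different sizes cannot be aligned")
    }
    ids <- sprintf("obs_%03d", seq_len(nrow(datasets[[1]])))
    datasets <- lapply(datasets, function(d) { rownames(d) <- ids; d })
  }
  ids <- unique(unlist(lapply(datasets, rownames)))
  n <- length(ids)
  m <- length(datasets)
  observed <- vapply(datasets, function(d) ids %in% rownames(d), logical(n))
  observed <- matrix(observed, nrow = n,
                     dimnames = list(ids, names(datasets)))
  if (any(rowSums(observed) == 0)) {
    alignment_error("every observation must be present in at least one dataset")
  }
  if (is.null(k_per_dataset)) {
    k_per_dataset <- if (!is.null(K)) K else max(k_range)
  }
  k_per_dataset <- rep_len(as.integer(k_per_dataset), m)
  kernels <- vector("list", m)
  # key the per-dataset random stream by name where available, so permuting
  # the dataset order reproduces the same consensus matrix per dataset
  ds_keys <- names(datasets) %||% as.character(seq_len(m))
  ds_keys[!nzchar(ds_keys)] <- as.character(which(!nzchar(ds_keys)))
  for (j in seq_len(m)) {
    d <- datasets[[j]]
    cl <- if (!is.null(clusterers)) clusterers[[j]] else NULL
    cm <- consensus_cluster(d, k_per_dataset[j], n_runs = n_runs,
                            item_proportion = item_proportion,
                            feature_proportion = feature_proportion,
                            method = method, clusterer = cl,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 31L, ds_keys[j]),
                            n_restarts = n_restarts)
    cm <- spectral_shift(unclass(cm))
    # embed into the full observation universe; missing rows/columns stay 0
    full <- matrix(0, n, n, dimnames = list(ids, ids))
    pos <- match(rownames(d), ids)
    full[pos, pos] <- cm
    kernels[[j]] <- full
  }
  names(kernels) <- names(datasets)
  res <- run_klic_from_kernels(kernels, K = K, k_range = k_range,
                               observed_mask = observed, tol = tol,
                               max_iter = max_iter, seed = seed,
                               n_restarts = n_restarts)
  res$per_dataset_consensus <- kernels
  res
}

#' @export
print.klic_result <- function(x, ...) {
  n <- length(x$labels)
  m <- ncol(x$weights)
  cat(sprintf("KLIC result: N = %d observations, M = %d kernel(s), K = %d clusters\n",
              n, m, x$k_selected))
  if (length(x$silhouette_by_k) > 1 || !is.na(x$silhouette_by_k[1])) {
    cat("average silhouette by K:",
        paste(sprintf("%s: %.3f", names(x$silhouette_by_k), x$silhouette_by_k),
              collapse = ", "), "\n")
  }
  w <- 100 * colMeans(x$weights)
  nm <- colnames(x$weights) %||% sprintf("kernel %d", seq_len(m))
  cat("mean weight per dataset (%):",
      paste(sprintf("%s %.1f", nm, w), collapse = ", "), "\n")
  cat(sprintf("objective %.6g after %d iteration(s)%s\n", x$objective,
              x$n_iter, if (x$converged) " (converged)" else ""))
  invisible(x)
}
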