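# Evaluation metrics (adjusted Rand index, silhouette widths), the RBF
# bandwidth-tuning oracle used in simulation comparisons, and a small heatmap
# helper.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same
#' observations (Hubert-Arabie adjustment under the permutation model): 1 for
#' identical partitions, about 0 for independent ones. The comparison is
#' symmetric and invariant to relabelling. When both vectors are named, the
#' intersection of their names is compared; `NA` labels are dropped pairwise.
#'
#' @param a,b Integer label vectors (named by observation ID or aligned
#'   positionally). At least 2 common observations are required.
#' @return The adjusted Rand index (single numeric).
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # identical up to labels
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]
    b <- b[common]
  } else if (length(a) != length(b)) {
    input_error("unnamed partitions must have the same length")
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 2) input_error("need at least 2 common observations")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  # common-denominator form keeps the arithmetic exact for integer counts
  num <- n2 * sum_ij - sum_a * sum_b
  den <- n2 * (sum_a + sum_b) / 2 - sum_a * sum_b
  if (den == 0) return(1)  # both partitions trivial in the same way
  num / den
}

#' Silhouette widths of a partition under a distance matrix
#'
#' Rousseeuw's silhouette: for each observation,
#' `s(i) = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean distance to
#' its own cluster and `b_i` the smallest mean distance to another cluster.
#' Observations in singleton clusters score 0, as does everything when there
#' is only one cluster.
#'
#' @param labels Integer cluster labels.
#' @param distance N x N symmetric distance matrix with zero diagonal.
#' @return List with `widths` (length-N numeric) and `average`.
#' @export
silhouette_widths <- function(labels, distance) {
  distance <- as.matrix(distance)
  check_square_symmetric(unclass(distance), tol = 1e-6, what = "distance")
  if (max(abs(diag(distance))) > 1e-8) {
    input_error("distance matrix must have a zero diagonal")
  }
  n <- nrow(distance)
  if (length(labels) != n) input_error("labels length must match the distance matrix")
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2 || max(tabulate(labels)) == 1) {
    # one cluster only, or all clusters singletons: every width is 0
    return(list(widths = rep(0, n), average = 0))
  }
  sil <- cluster::silhouette(labels, dmatrix = unclass(distance))
  widths <- sil[, "sil_width"]
  list(widths = as.numeric(widths), average = mean(widths))
}

#' Tune the RBF bandwidth against known labels
#'
#' Oracle comparator for simulation studies only: for each candidate
#' bandwidth, kernel k-means on the RBF kernel is repeated over seeded runs
#' and the bandwidth maximizing the mean adjusted Rand index against the true
#' labels is returned (ties towards the smallest bandwidth). This requires
#' the truth and therefore gives an upper bound on what an RBF-kernel
#' pipeline could achieve in practice.
#'
#' @param data Numeric observations x features matrix.
#' @param true_labels True cluster labels.
#' @param sigma_grid Numeric vector of candidate bandwidths.
#' @param K Number of clusters.
#' @param n_reps Seeded repetitions per candidate (default 5).
#' @param seed Base seed.
#' @return The selected bandwidth, with the per-candidate mean ARIs attached
#'   as the `ari_by_sigma` attribute.
#' @export
tune_rbf_sigma <- function(data, true_labels, sigma_grid, K, n_reps = 5,
                           seed = NULL) {
  if (length(sigma_grid) < 1) input_error("sigma_grid is empty")
  sigma_grid <- sort(unique(as.numeric(sigma_grid)))
  mean_ari <- vapply(seq_along(sigma_grid), function(g) {
    kern <- rbf_kernel(data, sigma_grid[g])
    mean(vapply(seq_len(n_reps), function(r) {
      lab <- kernel_kmeans(kern, K,
                           seed = if (is.null(seed)) NULL else derive_seed(seed, 41L, g, r))
      adjusted_rand_index(lab, true_labels)
    }, numeric(1)))
  }, numeric(1))
  structure(sigma_grid[which.max(mean_ari)],
            ari_by_sigma = stats::setNames(mean_ari, sigma_grid))
}

#' Basic kernel/consensus heatmap
#'
#' Draws a similarity matrix with [graphics::image()], optionally reordering
#' observations by cluster label so the block structure is visible.
#'
#' @param m N x N similarity matrix.
#' @param labels Optional cluster labels used to order the observations.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the row order used.
#' @export
plot_similarity_heatmap <- function(m, labels = NULL, ...) {
  m <- as.matrix(m)
  ord <- if (is.null(labels)) seq_len(nrow(m)) else order(labels)
  z <- m[ord, ord]
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), t(z[rev(seq_len(nrow(z))), ]),
                  xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE), ...)
  invisible(ord)
}
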