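# Kernel machinery: PSD checks and repair, RBF kernels, kernel k-means via
# spectral relaxation, weighted kernel combination, the QP weight update, and
# the localized multiple-kernel k-means loop.

#' Check positive semi-definiteness
#'
#' Reports the smallest eigenvalue of a symmetric matrix and whether it is
#' (numerically) positive semi-definite. Consensus matrices built without item
#' subsampling are PSD exactly; with item subsampling the pair-specific
#' denominators can push eigenvalues slightly below zero, hence the tolerance.
#'
#' @param m Square symmetric numeric matrix (asymmetry beyond 1e-8 is an
#'   error).
#' @param tol Nonnegative tolerance; PSD means `min eigenvalue >= -tol`.
#' @return List with `min_eigenvalue` and logical `is_psd`.
#' @examples
#' check_psd(diag(3))
#' check_psd(matrix(c(1, 2, 2, 1), 2))  # indefinite: eigenvalues 3 and -1
#' @export
check_psd <- function(m, tol = 1e-8) {
  check_square_symmetric(m, what = "kernel")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min_eig <- min(ev)
  list(min_eigenvalue = min_eig, is_psd = min_eig >= -tol)
}

#' Repair a near-PSD matrix by shifting its spectrum
#'
#' If the smallest eigenvalue is below `-tol`, adds `|min eigenvalue|` times
#' the identity, which makes the smallest eigenvalue exactly zero and leaves
#' the eigenvectors unchanged. PSD inputs are returned untouched. The applied
#' shift is recorded in the `spectral_shift` attribute (0 when no repair was
#' needed) and announced via [message()].
#'
#' @inheritParams check_psd
#' @return The (possibly shifted) matrix with attribute `spectral_shift`.
#' @export
spectral_shift <- function(m, tol = 1e-8) {
  psd <- check_psd(m, tol)
  shift <- 0
  if (!psd$is_psd) {
    shift <- -psd$min_eigenvalue
    m <- m + diag(shift, nrow(m))
    message(sprintf("spectral_shift: inflated diagonal by %.3g to repair min eigenvalue %.3g",
                    shift, psd$min_eigenvalue))
  }
  attr(m, "spectral_shift") <- shift
  m
}

#' Radial basis function kernel matrix
#'
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`, so the diagonal is 1 and
#' `sigma` is the length scale of the similarity.
#'
#' @param data Numeric observations x features matrix.
#' @param sigma Positive bandwidth (default 1).
#' @return N x N kernel matrix with row/column names from `data`.
#' @export
rbf_kernel <- function(data, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    input_error("sigma must be a single positive number")
  }
  d2 <- as.matrix(stats::dist(as.matrix(data)))^2
  exp(-d2 / (2 * sigma^2))
}

# Column-normalised cluster indicator: H[i, j] = 1/sqrt(n_j) when i is in
# cluster j, so the columns are orthonormal and H H' is the projection onto
# the cluster-indicator subspace.
indicator_normalized <- function(labels, K = max(labels)) {
  n <- length(labels)
  h <- matrix(0, n, K)
  h[cbind(seq_len(n), labels)] <- 1
  sizes <- colSums(h)
  keep <- sizes > 0
  h[, keep] <- sweep(h[, keep, drop = FALSE], 2, sqrt(sizes[keep]), `/`)
  h
}

# Kernel k-means objective of a labelling: tr(K) - tr(H' K H), i.e. the total
# within-cluster sum of squared distances in the feature space.
kernel_kmeans_objective <- function(kernel, labels) {
  total <- sum(diag(kernel))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    total <- total - sum(kernel[idx, idx]) / length(idx)
  }
  total
}

#' Kernel k-means via the kernel PCA embedding
#'
#' Embeds the observations as the rows of `V L^(1/2)` where `V, L` are the
#' eigenvectors and (nonnegative) eigenvalues of the kernel — the kernel
#' principal component scores — and runs restarted k-means on the embedding.
#' Squared Euclidean distances in this embedding equal feature-space
#' distances, so the k-means objective coincides with the kernel k-means
#' objective `tr(K) - tr(H' K H)` and the discretisation inherits k-means'
#' quality directly. Components with eigenvalues below `1e-10 * max(L)` are
#' dropped; small negative eigenvalues (repaired or not) are clipped at zero.
#' The reported objective is `tr(K) - tr(H' K H)` of the returned labels.
#'
#' @param kernel N x N PSD kernel matrix (run [spectral_shift()] first if in
#'   doubt).
#' @param K Number of clusters (1 <= K <= N).
#' @param seed Seed for the k-means discretisation step.
#' @param n_restarts k-means restarts.
#' @return Integer labels named by the kernel's row names, with the attribute
#'   `objective`.
#' @examples
#' k <- matrix(0, 4, 4); k[1:2, 1:2] <- 1; k[3:4, 3:4] <- 1
#' kernel_kmeans(k, K = 2, seed = 1)
#' @export
kernel_kmeans <- function(kernel, K, seed = NULL, n_restarts = 10) {
  check_square_symmetric(kernel, what = "kernel")
  n <- nrow(kernel)
  if (K < 1 || K > n) input_error(sprintf("K must be in 1..%d", n))
  eig <- tryCatch(eigen((kernel + t(kernel)) / 2, symmetric = TRUE),
                  error = function(e) {
                    numeric_error(paste("eigendecomposition failed:",
                                        conditionMessage(e)))
                  })
  values <- pmax(eig$values, 0)
  keep <- values > 1e-10 * max(values, 0)
  if (!any(keep)) keep[1] <- TRUE
  vectors <- eig$vectors[, keep, drop = FALSE]
  # deterministic sign convention: first component of modulus > 1e-8 positive
  for (j in seq_len(ncol(vectors))) {
    nz <- which(abs(vectors[, j]) > 1e-8)
    if (length(nz) > 0 && vectors[nz[1], j] < 0) vectors[, j] <- -vectors[, j]
  }
  scores <- sweep(vectors, 2, sqrt(values[keep]), `*`)
  labels <- kmeans_restart(scores, K, n_restarts = n_restarts, seed = seed)
  names(labels) <- rownames(kernel)
  attr(labels, "objective") <- kernel_kmeans_objective(kernel, labels)
  labels
}

#' Combine kernels with per-observation, per-dataset weights
#'
#' Entry (i, j) of the combined kernel is
#' `sum_m theta_im * theta_jm * K_m(i, j)`: a convex combination of the input
#' kernels localized per observation. The result is PSD whenever every input
#' is PSD, because each term is a PSD matrix congruence-scaled by a rank-one
#' nonnegative mask.
#'
#' @param kernels List of M kernel matrices, all N x N.
#' @param weights N x M nonnegative matrix; each row should sum to 1 over the
#'   datasets in which the observation is present.
#' @return N x N combined kernel matrix.
#' @export
combine_kernels <- function(kernels, weights) {
  if (length(kernels) < 1) input_error("need at least one kernel")
  n <- nrow(kernels[[1]])
  weights <- as.matrix(weights)
  if (nrow(weights) != n || ncol(weights) != length(kernels)) {
    input_error(sprintf("weights must be %d x %d", n, length(kernels)))
  }
  if (any(!vapply(kernels, function(k) all(dim(k) == n), TRUE))) {
    input_error("all kernels must be square with the same N")
  }
  out <- matrix(0, n, n)
  for (m in seq_along(kernels)) {
    out <- out + tcrossprod(weights[, m]) * unclass(kernels[[m]])
  }
  dimnames(out) <- dimnames(kernels[[1]])
  out
}

#' Weight update step: convex QP over per-observation simplices
#'
#' At fixed cluster assignments, the localized multiple-kernel k-means
#' objective as a function of the weights is
#' `sum_m theta_m' Q_m theta_m` with `Q_m = K_m * (I - H H')` (entrywise
#' product with the projection complementary to the normalised cluster
#' indicator H). Each `Q_m` is PSD by the Schur product theorem, so the
#' problem is a convex QP; it is solved exactly by cyclic block-coordinate
#' descent over observations (each row subproblem is a closed-form simplex
#' waterfilling step), which converges because the Hessian blocks couple only
#' within datasets while the constraints couple only within rows.
#'
#' @param kernels List of M PSD kernel matrices, all N x N.
#' @param assignment N x K column-normalised cluster indicator matrix (as
#'   built from the current labels; columns orthonormal).
#' @param observed_mask N x M logical matrix; `FALSE` entries force the
#'   corresponding weight to zero (missing observations). Default: all
#'   observed.
#' @param theta0 Optional feasible starting point (defaults to uniform over
#'   observed datasets). Starting from the current weights guarantees the
#'   update never increases the objective.
#' @param ridge Tiny diagonal regulariser making each row subproblem strictly
#'   convex; also the tie-break towards minimal-norm solutions.
#' @param max_sweeps,tol Solver iteration cap and per-sweep convergence
#'   threshold (max absolute weight change).
#' @return N x M weight matrix with attribute `objective` (the value of the
#'   QP objective, without ridge).
#' @export
update_weights_qp <- function(kernels, assignment, observed_mask = NULL,
                              theta0 = NULL, ridge = 1e-10,
                              max_sweeps = 1000, tol = 1e-8) {
  n <- nrow(kernels[[1]])
  m <- length(kernels)
  assignment <- as.matrix(assignment)
  if (nrow(assignment) != n) input_error("assignment must have N rows")
  if (is.null(observed_mask)) observed_mask <- matrix(TRUE, n, m)
  observed_mask <- as.matrix(observed_mask)
  if (!all(dim(observed_mask) == c(n, m))) {
    input_error("observed_mask must be N x M")
  }
  if (any(rowSums(observed_mask) == 0)) {
    alignment_error("every observation must be present in at least one dataset")
  }
  proj <- diag(n) - tcrossprod(assignment)
  qs <- lapply(kernels, function(k) unclass(k) * proj)
  if (is.null(theta0)) {
    theta0 <- observed_mask / rowSums(observed_mask)
  } else {
    theta0 <- as.matrix(theta0)
    theta0[!observed_mask] <- 0
  }
  sol <- solve_row_simplex_qp(qs, observed_mask, theta0,
                              ridge = ridge, max_sweeps = max_sweeps, tol = tol)
  if (!sol$converged) {
    numeric_error(sprintf(
      "weight QP did not converge in %d sweeps (last objective %.6g)",
      sol$sweeps, sol$objective))
  }
  structure(sol$theta,
            objective = sol$objective,
            dimnames = list(rownames(kernels[[1]]), names(kernels)))
}

#' Localized multiple-kernel k-means
#'
#' Alternates (i) kernel k-means on the weighted combined kernel at fixed
#' weights with (ii) the convex QP weight update at fixed assignments,
#' starting from weights uniform over the datasets observing each item. The
#' assignment step follows a spectral relaxation, so the objective need not
#' decrease monotonically across outer iterations; the loop stops when the
#' relative change of the assignment-step objective is at most `tol` (or
#' after `max_iter` iterations) and the best-objective iterate is returned.
#'
#' @inheritParams update_weights_qp
#' @param K Number of clusters.
#' @param tol Relative objective-change stopping threshold (default 1e-5;
#'   `Inf` stops after a single assignment pass, leaving the weights at their
#'   uniform initialisation).
#' @param max_iter Outer iteration cap (default 100).
#' @param seed Seed for the assignment steps (the same seed is used in each
#'   outer iteration, so a single-kernel run reproduces [kernel_kmeans()]
#'   exactly).
#' @param n_restarts k-means restarts in the discretisation step.
#' @return An object of class `mkl_fit`: list with `labels`, `weights`,
#'   `combined_kernel`, `objective`, `objective_trace` (data frame with the
#'   assignment- and weight-step objectives per iteration), `n_iter`, and
#'   `converged`.
#' @export
localized_mkl_kmeans <- function(kernels, K, observed_mask = NULL,
                                 tol = 1e-5, max_iter = 100, seed = NULL,
                                 n_restarts = 10) {
  if (length(kernels) < 1) input_error("need at least one kernel")
  n <- nrow(kernels[[1]])
  m <- length(kernels)
  for (k in kernels) check_square_symmetric(k, what = "kernel")
  if (any(!vapply(kernels, function(k) nrow(k) == n, TRUE))) {
    input_error("all kernels must have the same N")
  }
  if (is.null(observed_mask)) observed_mask <- matrix(TRUE, n, m)
  if (any(rowSums(observed_mask) == 0)) {
    alignment_error("every observation must be present in at least one dataset")
  }
  theta <- observed_mask / rowSums(observed_mask)
  prev_obj <- NULL
  best <- NULL
  trace <- data.frame(iteration = integer(), objective_assignment = numeric(),
                      objective_weights = numeric())
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    combined <- combine_kernels(kernels, theta)
    if (all(abs(combined) < 1e-12)) {
      numeric_error("combined kernel is identically zero")
    }
    labels <- kernel_kmeans(combined, K, seed = seed, n_restarts = n_restarts)
    obj <- attr(labels, "objective")
    if (is.null(best) || obj < best$objective) {
      best <- list(labels = labels, weights = theta, combined_kernel = combined,
                   objective = obj)
    }
    rel <- if (is.null(prev_obj)) Inf else
      abs(obj - prev_obj) / max(abs(prev_obj), 1e-12)
    trace <- rbind(trace, data.frame(iteration = it,
                                     objective_assignment = obj,
                                     objective_weights = NA_real_))
    if (rel <= tol) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
    if (it == max_iter) break
    h <- indicator_normalized(labels, K)
    theta <- update_weights_qp(kernels, h, observed_mask, theta0 = theta)
    trace$objective_weights[it] <- attr(theta, "objective")
  }
  weights_out <- unclass(best$weights)
  attr(weights_out, "objective") <- NULL
  dimnames(weights_out) <- list(rownames(kernels[[1]]), names(kernels))
  structure(list(labels = best$labels,
                 weights = weights_out,
                 combined_kernel = best$combined_kernel,
                 objective = best$objective,
                 objective_trace = trace,
                 n_iter = n_iter,
                 converged = converged),
            class = "mkl_fit")
}

#' @export
print.mkl_fit <- function(x, ...) {
  cat(sprintf("Localized multiple-kernel k-means fit: N = %d, M = %d, K = %d\n",
              length(x$labels), ncol(x$weights),
              length(unique(x$labels))))
  cat(sprintf("objective %.6g after %d iteration(s)%s\n", x$objective,
              x$n_iter, if (x$converged) " (converged)" else ""))
  cat("mean kernel weights (%):",
      paste(sprintf("%.1f", 100 * colMeans(x$weights)), collapse = ", "), "\n")
  invisible(x)
}
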