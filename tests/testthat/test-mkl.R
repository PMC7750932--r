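test_that("PSD check reports the smallest eigenvalue", {
  expect_equal(check_psd(diag(2))$min_eigenvalue, 1)
  res <- check_psd(matrix(c(1, 2, 2, 1), 2))
  expect_equal(res$min_eigenvalue, -1)
  expect_false(res$is_psd)
  # any co-clustering matrix is PSD
  for (r in 1:10) {
    cc <- coclustering_matrix(random_partition(20, 4, seed = r))
    expect_true(check_psd(cc)$is_psd)
  }
  asym <- matrix(c(1, 0, 1, 1), 2)
  expect_error(check_psd(asym), class = "kliclust_input_error")
})

test_that("spectral shift repairs exactly to a zero floor", {
  m <- matrix(c(1, 2, 2, 1), 2)
  shifted <- suppressMessages(spectral_shift(m))
  expect_equal(unclass(shifted), matrix(2, 2, 2), ignore_attr = TRUE)
  expect_equal(attr(shifted, "spectral_shift"), 1)
  expect_equal(check_psd(unclass(shifted))$min_eigenvalue, 0)

  psd <- random_psd(5, seed = 1)
  expect_equal(unclass(spectral_shift(psd)), psd, ignore_attr = TRUE)
  z <- matrix(0, 3, 3)
  expect_equal(unclass(spectral_shift(z)), z, ignore_attr = TRUE)
})

test_that("RBF kernel follows exp(-d^2 / (2 sigma^2))", {
  x <- rbind(c(0, 0), c(1, 0), c(0, 3))
  k <- rbf_kernel(x, sigma = 1)
  expect_equal(diag(k), rep(1, 3), ignore_attr = TRUE)
  expect_equal(k[1, 2], exp(-0.5))
  expect_equal(k[1, 3], exp(-4.5))
  wide <- rbf_kernel(x, sigma = 1e6)
  expect_true(all(abs(wide - 1) < 1e-9))
  expect_error(rbf_kernel(x, sigma = 0), class = "kliclust_input_error")
})

test_that("kernel k-means recovers exact block structure and the K = 1 form", {
  k <- two_block_kernel(c(6, 4))
  lab <- kernel_kmeans(k, 2, seed = 1)
  expect_equal(adjusted_rand_index(lab, rep(1:2, c(6, 4))), 1)

  one <- kernel_kmeans(k, 1)
  expect_equal(unique(as.integer(one)), 1L)
  expect_equal(attr(one, "objective"),
               sum(diag(k)) - sum(k) / nrow(k))
})

test_that("kernel k-means matches the exhaustive bipartition oracle", {
  for (r in 1:8) {
    kern <- random_psd(8, seed = 50 + r)
    obj <- attr(kernel_kmeans(kern, 2, seed = r), "objective")
    expect_lte(obj, 1.05 * brute_force_k2_objective(kern) + 1e-10)
  }
})

test_that("kernel combination follows the localized convex sum", {
  k1 <- random_psd(4, seed = 1)
  k2 <- random_psd(4, seed = 2)
  w1 <- matrix(1, 4, 1)
  expect_equal(combine_kernels(list(k1), w1), k1, ignore_attr = TRUE)

  half <- matrix(0.5, 4, 2)
  expect_equal(combine_kernels(list(k1, k2), half), (k1 + k2) / 4,
               ignore_attr = TRUE)

  w <- cbind(rep(1, 4), rep(0, 4))
  expect_equal(combine_kernels(list(k1, k2), w), k1, ignore_attr = TRUE)

  # PSD is preserved under combination
  for (r in 1:10) {
    ks <- list(random_psd(6, seed = 3 * r), random_psd(6, seed = 3 * r + 1))
    th <- withr::with_seed(3 * r + 2, matrix(runif(12), 6))
    th <- th / rowSums(th)
    expect_gte(check_psd(combine_kernels(ks, th))$min_eigenvalue, -1e-8)
  }
})

test_that("weight QP: constraint-forced and symmetric solutions", {
  h <- kliclust:::indicator_normalized(rep(1:2, each = 3), 2)
  k1 <- random_psd(6, seed = 4)
  w <- update_weights_qp(list(k1), h)
  expect_equal(unclass(w), matrix(1, 6, 1), ignore_attr = TRUE)

  # identical kernels with strictly convex blocks: the unique optimum is 1/2
  w2 <- update_weights_qp(list(k1, k1), h, ridge = 1e-8)
  expect_equal(unclass(w2), matrix(0.5, 6, 2), ignore_attr = TRUE,
               tolerance = 1e-4)
})

test_that("weight QP matches the 0.01-step simplex grid oracle", {
  h3 <- kliclust:::indicator_normalized(c(1L, 2L, 2L), 2)
  p3 <- diag(3) - tcrossprod(h3)
  for (r in 1:8) {
    k1 <- random_psd(3, seed = 70 + r)
    k2 <- random_psd(3, seed = 170 + r)
    w <- update_weights_qp(list(k1, k2), h3)
    expect_lte(attr(w, "objective"),
               grid_qp_objective(k1 * p3, k2 * p3) + 1e-4)
  }
})

test_that("weight QP agrees with an interior-point solver", {
  # independent route: kernlab::ipop on the stacked N*M-variable QP
  h <- kliclust:::indicator_normalized(c(1L, 1L, 2L, 2L, 2L), 2)
  p <- diag(5) - tcrossprod(h)
  k1 <- random_psd(5, seed = 91)
  k2 <- random_psd(5, seed = 92)
  big_h <- 2 * rbind(cbind(k1 * p, matrix(0, 5, 5)),
                     cbind(matrix(0, 5, 5), k2 * p)) + diag(1e-8, 10)
  amat <- cbind(diag(5), diag(5))
  sol <- kernlab::ipop(c = rep(0, 10), H = big_h, A = amat, b = rep(1, 5),
                       l = rep(0, 10), u = rep(1, 10), r = rep(0, 5))
  th_ipop <- matrix(kernlab::primal(sol), 5, 2)
  obj_ipop <- sum(th_ipop[, 1] * ((k1 * p) %*% th_ipop[, 1])) +
    sum(th_ipop[, 2] * ((k2 * p) %*% th_ipop[, 2]))
  w <- update_weights_qp(list(k1, k2), h)
  expect_lte(attr(w, "objective"), obj_ipop + 1e-5)
  expect_equal(unclass(w), unclass(th_ipop), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("the Schur-product Hessian blocks stay PSD", {
  for (r in 1:10) {
    labels <- random_partition(10, 3, seed = 500 + r)
    h <- kliclust:::indicator_normalized(labels, 3)
    p <- diag(10) - tcrossprod(h)
    q <- random_psd(10, seed = 600 + r) * p
    expect_gte(check_psd(q)$min_eigenvalue, -1e-8)
  }
})

test_that("the alternating loop: weight rows conserve mass and QP never increases the objective", {
  ks <- list(two_block_kernel(c(5, 5)) + diag(0.1, 10),
             random_psd(10, seed = 7) / 10)
  fit <- localized_mkl_kmeans(ks, K = 2, seed = 3)
  expect_equal(rowSums(fit$weights), rep(1, 10), ignore_attr = TRUE)
  tr <- fit$objective_trace
  done <- !is.na(tr$objective_weights)
  expect_true(all(tr$objective_weights[done] <=
                    tr$objective_assignment[done] + 1e-8))
})

test_that("informative kernels outweigh pure noise", {
  blk <- two_block_kernel(c(10, 10))
  fit <- localized_mkl_kmeans(list(signal = blk, noise = diag(20)), K = 2,
                              seed = 1)
  expect_gt(mean(fit$weights[, "signal"]), mean(fit$weights[, "noise"]))
  expect_equal(adjusted_rand_index(fit$labels, rep(1:2, each = 10)), 1)
})

test_that("single-kernel runs reduce exactly to kernel k-means", {
  for (r in 1:20) {
    kern <- random_psd(12, seed = 700 + r)
    fit <- localized_mkl_kmeans(list(kern), K = 3, seed = r)
    direct <- kernel_kmeans(kern, 3, seed = r)
    expect_identical(as.integer(fit$labels), as.integer(direct))
  }
})

test_that("tol = Inf stops after one assignment pass with uniform weights", {
  ks <- list(two_block_kernel(c(4, 4)), diag(8))
  fit <- localized_mkl_kmeans(ks, K = 2, seed = 2, tol = Inf)
  expect_equal(fit$n_iter, 1L)
  expect_true(all(fit$weights == 0.5))
  expect_error(localized_mkl_kmeans(list(matrix(0, 4, 4)), K = 2, seed = 1),
               class = "kliclust_numeric_error")
})
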