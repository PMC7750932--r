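test_that("co-clustering matrices follow the masked definition", {
  expect_equal(coclustering_matrix(c(1, 1, 2)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)), ignore_attr = TRUE)
  expect_equal(coclustering_matrix(rep(4, 5)), matrix(1, 5, 5),
               ignore_attr = TRUE)
  # excluded item: zero row/column including the diagonal
  expect_equal(coclustering_matrix(c(1, 1, NA)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 0)), ignore_attr = TRUE)
  expect_error(coclustering_matrix(c(1, 2), n_items = 3),
               class = "kliclust_input_error")
})

test_that("co-clustering is invariant to relabelling", {
  for (r in 1:10) {
    labels <- random_partition(12, 4, seed = r)
    perm <- withr::with_seed(100 + r, sample(4))
    expect_identical(coclustering_matrix(labels),
                     coclustering_matrix(perm[labels]))
  }
})

test_that("subsampling is deterministic and has forced sizes", {
  s1 <- subsample(10, 5, item_proportion = 0.8, seed = 1, run_index = 3)
  s2 <- subsample(10, 5, item_proportion = 0.8, seed = 1, run_index = 3)
  expect_identical(s1, s2)
  expect_length(s1$items, 8)
  expect_false(anyDuplicated(s1$items) > 0)
  s3 <- subsample(10, 5, item_proportion = 1, seed = 1, run_index = 3)
  expect_identical(s3$items, 1:10)
  expect_error(subsample(2, 5, item_proportion = 0.4, seed = 1),
               class = "kliclust_config_error")
})

test_that("the consensus matrix is the guarded co-clustering ratio", {
  # run 1: all three items, labels (1,1,2); run 2: items {1,3} co-clustered
  run1 <- coclustering_matrix(c(1, 1, 2))
  run2 <- coclustering_matrix(c(1, NA, 1))
  cm <- consensus_matrix(list(run1, run2))
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], 0.5)
  expect_equal(cm[2, 3], 0)
  expect_equal(diag(unclass(cm)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(attr(cm, "copair_counts")[1, 3], 2)

  # identical full-inclusion runs reproduce the common co-clustering matrix
  cm2 <- consensus_matrix(rep(list(run1), 7))
  expect_equal(unclass(cm2), unclass(run1), ignore_attr = TRUE)

  # a pair never co-sampled stays at 0 by the denominator guard
  ra <- coclustering_matrix(c(1, 1, NA))
  rb <- coclustering_matrix(c(1, 1, NA))
  cm3 <- consensus_matrix(list(ra, rb))
  expect_equal(cm3[1, 3], 0)
  expect_equal(cm3[3, 3], 0)
})

test_that("consensus matrices are symmetric with entries in [0,1]", {
  for (r in 1:20) {
    runs <- lapply(1:5, function(h) {
      labels <- random_partition(15, 3, seed = 10 * r + h)
      drop <- withr::with_seed(1000 + 10 * r + h, sample(15, 4))
      labels[drop] <- NA
      coclustering_matrix(labels)
    })
    cm <- consensus_matrix(runs)
    expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
    expect_true(all(cm >= 0 & cm <= 1))
    sampled <- diag(attr(cm, "copair_counts")) > 0
    expect_equal(diag(unclass(cm))[sampled], rep(1, sum(sampled)),
                 ignore_attr = TRUE)
  }
})

test_that("adding an identical run pulls entries toward that run's values", {
  base <- lapply(1:4, function(h) coclustering_matrix(random_partition(10, 3, seed = h)))
  extra <- coclustering_matrix(random_partition(10, 3, seed = 99))
  before <- consensus_matrix(base)
  after <- consensus_matrix(c(base, list(extra)))
  moved <- ifelse(extra == 1, after >= before - 1e-12, after <= before + 1e-12)
  expect_true(all(moved))
})

test_that("feature-only resampling gives the plain co-clustering average, PSD", {
  sim <- generate_dataset(1, n_per_cluster = 8, seed = 2)
  h <- 15
  cm <- consensus_cluster(sim$data, K = 3, n_runs = h, item_proportion = 1,
                          feature_proportion = 1, seed = 4)
  # reconstruct the average of the co-clustering matrices independently
  runs <- lapply(seq_len(h), function(i) {
    coclustering_matrix(cluster_data(sim$data, 3,
                                     seed = kliclust:::derive_seed(4, 13L, i)))
  })
  expect_equal(unclass(cm), Reduce(`+`, runs) / h, ignore_attr = TRUE)
  expect_gte(check_psd(unclass(cm))$min_eigenvalue, -1e-8)
})

test_that("consensus entries are near-binary for separable data, ambiguous for noise", {
  clean <- generate_dataset(5, seed = 31)
  cm <- consensus_cluster(clean$data, K = 6, n_runs = 50, seed = 31)
  off <- cm[row(cm) != col(cm)]
  expect_lt(mean(off > 0.1 & off < 0.9), 0.05)

  noise <- generate_dataset(0, seed = 32)
  cm0 <- consensus_cluster(noise$data, K = 6, n_runs = 50, seed = 32)
  off0 <- cm0[row(cm0) != col(cm0)]
  # structureless data leaves many pairs ambiguous, an order of magnitude
  # more than the separable case above
  expect_gt(mean(off0 > 0.1 & off0 < 0.9), 0.15)
  expect_gt(mean(off0 > 0.1 & off0 < 0.9),
            5 * mean(off > 0.1 & off < 0.9))

  # item_proportion = 1 with a deterministic clusterer: exactly binary
  det <- function(x, k, seed) cluster_data(x, k, method = "hier_average")
  cmd <- consensus_cluster(clean$data, K = 6, n_runs = 5, item_proportion = 1,
                           clusterer = det, seed = 1)
  expect_true(all(cmd %in% c(0, 1)))
})

test_that("the ambiguity-proportion rule picks the right K", {
  binary <- two_block_kernel(c(3, 3))
  fuzzy <- matrix(0.5, 6, 6)
  diag(fuzzy) <- 1
  expect_equal(select_k_monti(list(`2` = binary, `3` = fuzzy)), 2L)
  # ties go to the smallest K
  expect_equal(select_k_monti(list(`4` = binary, `2` = binary)), 2L)
  expect_error(select_k_monti(list()), class = "kliclust_input_error")
})

test_that("consensus-based K selection recovers six clusters among fine candidates", {
  # With equally spaced collinear cluster means, merging adjacent clusters is
  # itself perfectly stable, so the ambiguity-proportion heuristic ties K = 2
  # and K = 3 with the truth; it discriminates among candidates at or above
  # the true resolution, where only K = 6 avoids arbitrary splits.
  hits <- 0
  for (r in 1:10) {
    sim <- generate_dataset(5, n_per_cluster = 15, seed = 200 + r)
    by_k <- lapply(stats::setNames(4:8, 4:8), function(k) {
      consensus_cluster(sim$data, K = k, n_runs = 25, seed = 200 + r)
    })
    if (select_k_monti(by_k) == 6) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("cluster_data covers its methods and edge cases", {
  two <- matrix(c(0, 0, 10, 10), 2, byrow = TRUE)
  expect_setequal(cluster_data(two, 2, seed = 1), 1:2)
  expect_error(cluster_data(two, 3), class = "kliclust_input_error")

  # strong signal: k-means recovers the truth in nearly every rep
  hits <- 0
  for (r in 1:10) {
    sim <- generate_dataset(5, seed = 300 + r)
    ari <- adjusted_rand_index(cluster_data(sim$data, 6, seed = r), sim$labels)
    if (ari == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # PAM with correlation distance on a 4-point toy, against a brute-force
  # medoid search over all medoid pairs
  toy <- rbind(c(1, 2, 3), c(2, 4, 6.2), c(3, 2, 1), c(6.1, 4, 2))
  d <- 1 - stats::cor(t(toy))
  best <- NULL
  for (i in 1:3) for (j in (i + 1):4) {
    assign_cost <- sum(pmin(d[, i], d[, j]))
    if (is.null(best) || assign_cost < best$cost) {
      best <- list(cost = assign_cost, labels = ifelse(d[, i] <= d[, j], 1L, 2L))
    }
  }
  got <- cluster_data(toy, 2, method = "pam", distance = "correlation")
  expect_equal(adjusted_rand_index(got, best$labels), 1)
})
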