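# Shared fixtures and independent oracles, all built in code.

# random PSD Gram matrix (Wishart-style)
random_psd <- function(n, seed) {
  withr::with_seed(seed, crossprod(matrix(rnorm(n * n), n)))
}

random_partition <- function(n, K, seed) {
  withr::with_seed(seed, sample.int(K, n, replace = TRUE))
}

# exact block kernel: two all-ones blocks
two_block_kernel <- function(sizes = c(10, 10)) {
  n <- sum(sizes)
  k <- matrix(0, n, n)
  k[seq_len(sizes[1]), seq_len(sizes[1])] <- 1
  k[(sizes[1] + 1):n, (sizes[1] + 1):n] <- 1
  k
}

# Pair-counting adjusted Rand oracle, independent of the contingency-table
# route: count concordant/discordant pairs directly.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)  # both partitions trivial in the same way
  2 * (n11 * n00 - n10 * n01) / denom
}

# Exhaustive kernel-2-means oracle: minimum objective over all bipartitions.
brute_force_k2_objective <- function(kernel) {
  n <- nrow(kernel)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g1 <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    labels <- rep(2L, n)
    labels[g1] <- 1L
    best <- min(best, kliclust:::kernel_kmeans_objective(kernel, labels))
  }
  best
}

# Brute-force QP oracle: 0.01-step grid over the per-row simplex, M = 2.
grid_qp_objective <- function(q1, q2) {
  n <- nrow(q1)
  stopifnot(n == 3)
  g <- seq(0, 1, by = 0.01)
  gr <- as.matrix(expand.grid(g, g, g))
  vals <- numeric(nrow(gr))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      vals <- vals + q1[i, j] * gr[, i] * gr[, j] +
        q2[i, j] * (1 - gr[, i]) * (1 - gr[, j])
    }
  }
  min(vals)
}
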