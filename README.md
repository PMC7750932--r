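# kliclust

Integrative clustering of multiple datasets that measure the *same*
observations — the typical multi-omic setting where tumour samples (or
genes) are profiled on several platforms and a single global partition is
wanted.

The package implements two complementary methods plus everything needed to
study them:

* **KLIC** (Kernel Learning Integrative Clustering). Resampled consensus
  clustering of each dataset yields a consensus matrix
  `Δ_ij = (# runs co-clustering i,j) / (# runs co-sampling i,j)`.
  Consensus matrices are positive semi-definite, hence valid kernels, and
  are combined by **localized multiple-kernel k-means**: with per-sample,
  per-dataset weights θ (each row on the simplex), kernel k-means is run on

      Δ_Θ(i,j) = Σ_m θ_im θ_jm Δ_m(i,j)

  alternating cluster assignment (kernel k-means via the kernel PCA
  embedding) with a convex quadratic program for Θ
  (`min Σ_m θ_m' [Δ_m ∘ (I − HH')] θ_m`). Informative datasets receive
  larger weights; samples missing from a dataset get weight 0 there.
* **COCA** (Cluster-Of-Clusters Analysis). Per-dataset partitions are
  one-hot stacked into a matrix of clusters (MOC), consensus clustering is
  applied to the MOC columns, and the final partition comes from
  average-linkage hierarchical clustering on `1 − Δ`. Unweighted, needs only
  labels — the classical comparator.

Support modules: synthetic Gaussian-cluster benchmark generators
(`generate_dataset()`, `generate_similar_collection()`,
`generate_heterogeneous_collection()`), adjusted Rand index and silhouette
evaluation, two selectors for the number of clusters, CSV/JSON input-output
and a command-line shell (`inst/cli/kliclust.R`).

## Worked example

Four data views sharing one 6-cluster structure, combined by KLIC:

```r
library(kliclust)

coll <- generate_similar_collection(4, separability = 2,
                                    n_per_cluster = 20, seed = 1)
res <- run_klic(lapply(coll, `[[`, "data"), K = 6, n_runs = 100, seed = 1)
#> spectral_shift: inflated diagonal by 0.133 to repair min eigenvalue -0.133
#> (one such message per item-resampled consensus matrix)
res
#> KLIC result: N = 120 observations, M = 4 kernel(s), K = 6 clusters
#> mean weight per dataset (%): A 18.9, B 28.3, C 21.5, D 31.3
#> objective 8.96663 after 3 iteration(s) (converged)

adjusted_rand_index(res$labels, coll[[1]]$labels)
#> [1] 0.9593184

# each single view alone does worse:
sapply(res$per_dataset_consensus, function(k)
  adjusted_rand_index(kernel_kmeans(unclass(k), 6, seed = 1), coll[[1]]$labels))
#>         A         B         C         D 
#> 0.5620281 0.7360136 0.7235844 0.8262926
```

The combined partition (ARI 0.96 against the truth) is closer to the truth
than any single view (ARI 0.56–0.83), and the weight shares track how well
each view's consensus matrix happens to resolve the clusters in this draw
(D, the cleanest, gets the most). Averaged over seeds the four equally noisy
views converge to equal ~25% shares; with views of systematically *unequal*
quality the weights shift durably towards the cleaner views — that is the
point of the method.

## Command line

```sh
Rscript inst/cli/kliclust.R simulate  --scenario heterogeneous --s 0,1,2,3 --seed 1 --outdir data/
Rscript inst/cli/kliclust.R consensus --input data/dataset_0.csv --k 6 --runs 1000 --seed 1 --out delta.csv
Rscript inst/cli/kliclust.R klic      --inputs data/dataset_0.csv,data/dataset_3.csv --k 6 --seed 1 --outdir out/
Rscript inst/cli/kliclust.R evaluate  --labels out/labels.csv --truth data/truth.csv
```
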