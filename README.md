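# adaknn

Adaptive k-nearest-neighbor graph clustering for single-cell and spatial
transcriptomics, built to detect **abundant and rare cell populations
simultaneously**.

## The problem and the method

Standard graph-based clustering (the Seurat-style pipeline) connects
every cell to a fixed number `k` of nearest neighbors in PCA space and
partitions the graph with Louvain community detection. A population with
fewer than `k` cells cannot form its own neighborhood: its members are
forced into long-range edges that weld them onto an abundant cluster, and
no resolution setting recovers them. Lowering `k` globally instead
shatters the abundant populations.

`adaknn` chooses `k` per cell from the cell's own sorted neighbor
distances d<sub>i1</sub> ≤ … ≤ d<sub>iK<sub>max</sub></sub>, using the
closed-form cutoff

$$d_{\mathrm{cutoff}}(i)=\left(\frac{\sum_{l=1}^{K_{\max}}\sqrt{d_{il}}}{K_{\max}-1-\delta}\right)^{2},\qquad
k_i=\#\{l: d_{il}<d_{\mathrm{cutoff}}(i)\},$$

with δ ≤ 0 (default −0.5) tuning the sensitivity to local distance
change. A cell in a tight rare population sees a sharp distance jump once
its population is exhausted and keeps only the neighbors before the jump;
a cell inside an abundant population keeps all K<sub>max</sub>. The
directed adaptive graph is reweighted by the Jaccard similarity of
neighbor sets (shared-nearest-neighbor graph, pruned at 1/15) and
clustered with seeded Louvain at a chosen resolution. An optional grid
search (`optimize_delta()`) walks δ downward and stops just before the
community count jumps — the signature of overclustering.

The package also ships the surrounding pipeline (cell/gene filtering,
10,000-UMI log-normalization, vst highly-variable-gene selection, PCA),
evaluation metrics (Adjusted Rand Index, rare-cell detection accuracy), a
negative-binomial simulator with planted cell types, 10x MatrixMarket and
CSV readers, and broom-style `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a hard case — two abundant types of 200 cells and one rare type
of 10, markers on 5% of genes — and cluster it:

```r
library(adaknn)

sim <- simulate_counts(simulation_design(type_sizes = c(200, 200, 10),
                                         seed = 1))
cl <- run_adaknn(sim, n_hvg = 500, n_pcs = 30, seed = 1)
cl
#> <aknn_clustering> 410 cells, 3 communities (resolution 0.8, delta -0.5)
#> sizes: 200, 200, 10

table(cluster = cl$labels, truth = cell_labels(sim))
#>        truth
#> cluster type1 type2 type3
#>       0   200     0     0
#>       1     0   200     0
#>       2     0     0    10

evaluate_clustering(cl, cell_labels(sim), rare_type = "type3")
#> # A tibble: 1 × 3
#>     ari n_communities rare_accuracy
#>   <dbl>         <int>         <dbl>
#> 1     1             3             1
```

All three planted types are recovered exactly (ARI 1): the ten rare cells
were assigned k<sub>i</sub> between 8 and 11 — their true within-type
neighborhoods — while abundant cells kept ≈ 17 neighbors on average. The
conventional fixed-k graph on the same embedding shows the failure mode
the method exists to fix:

```r
clf <- run_adaknn(sim, method = "fixed", n_hvg = 500, n_pcs = 30,
                  resolution = 0.1, seed = 1)
evaluate_clustering(clf, cell_labels(sim), rare_type = "type3")
#> # A tibble: 1 × 3
#>     ari n_communities rare_accuracy
#>   <dbl>         <int>         <dbl>
#> 1 0.952             2             0
```

At resolution 0.1 the fixed-k baseline absorbs every rare cell into an
abundant cluster (`rare_accuracy` 0), while the adaptive graph at the
same resolution still recovers all ten. See
`vignettes/adaptive-knn-clustering.Rmd` for the model, the δ grid
search, preprocessing conventions and the simulator's design.

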