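# stisebs

Superpixel segmentation for dense spatial time series.

Long, high-resolution satellite time series — for example 20 years of 8-day,
250 m NDVI over a region of several hundred thousand pixels — are too large
for many environmental analyses, so practitioners routinely fall back on
coarser pixels and accept the subpixel heterogeneity that comes with them.
`stisebs` implements **STiSeBS** (Spatial Time Series-Based Superpixels), an
unsupervised algorithm that instead groups adjacent pixels whose *entire
time series* are similar, reducing spatial dimensionality with far less
information loss than coarse pixels, while keeping every retained component
of the temporal signal (unlike SLIC-style methods that are limited to three
feature channels).

## The algorithm

Given an `H x W x T` vegetation-index grid with per-pixel series
`NDVI_i = (NIR_i - Red_i) / (NIR_i + Red_i)`, cleaned by range filtering to
`[-1, 1]`, exponential-weighted gap filling and Savitzky–Golay smoothing:

1. **Reduce** — PCA over pixels with periods as variables; keep the smallest
   `C` leading components explaining a variance target (default 99 %,
   capped at 200). Pixel `i` becomes a score vector `x_i ∈ R^C`.
2. **Cluster** — seeded k-means (k-means++ initialization, Lloyd
   iterations) on all retained components; deliberately *non-spatial*.
3. **Dissolve** — contiguous (rook) pixels of one cluster become patches;
   patch `j` carries the mean score vector
   `x_j = (1/H_j) Σ_{i∈j} x_i`.
4. **Regionalize (SKATER)** — build the patch adjacency graph with edge
   cost `||x_a − x_b||₂`, reduce it to a minimum spanning tree (Prim), and
   prune greedily: at each step remove the single edge, over all current
   trees, that minimizes the total intracluster square deviation
   `SSD_k = (1/n_k) Σ_{j∈k} ||x_j − x̄_k||²`, until `k` superpixels exist.
5. **Assemble** — each superpixel's series is the unweighted mean of its
   member pixels' series.

Assessment follows the standard protocol: superpixels are disassembled back
to their constituent pixels, each carrying its superpixel's mean series, and
scored by the cumulative Euclidean deviation `Σ_i ||NDVI_i − N̂DVI_i||₂`,
inhomogeneity δ (mean pairwise within-superpixel series distance, lower
better) and isolation γ (mean distance to adjacent superpixels), and — given
a land-cover map — majority-label classification accuracy (overall accuracy,
kappa from exact marginals, per-class precision/sensitivity/F1/MCC).
Baselines: coarse `f x f` pixel blocks, and e-SLIC (SLIC on the top three
principal components).

## Worked example

```r
library(stisebs)

# a 64 x 64 grid, two synthetic years of 8-day NDVI, six regions,
# noise sd 0.02, 2% missing observations
scene <- generate_scene(scene_spec(seed = 1))
scene$grid
#> <ts_grid> 64 x 64 x 92, 4096 valid pixels

res <- run_stisebs(scene$grid, k_superpixels = 6, seed = 1, preprocess = TRUE)
res$pca
#> <pca_model> 92 -> 3 components (99.49% of variance, target 99%)
res$superpixels
#> <superpixel_set> 6 segments over 4096 pixels, T=92

unlist(score_recovery(res$labels, scene$truth))
#>             ari boundary_recall   achievable_oa
#>               1               1               1

ndvi <- res$grid                       # the preprocessed stack
err_sp <- euclidean_error(ndvi, broadcast_to_hr(res$superpixels))$total
coarse <- coarse_pixel_baseline(ndvi, factor = 4)
err_lr <- euclidean_error(ndvi, broadcast_to_hr(coarse$superpixels))$total
cat(sprintf("superpixels %.1f vs coarse blocks %.1f (-%.1f%%)\n",
            err_sp, err_lr, 100 * (1 - err_sp / err_lr)))
#> superpixels 462.8 vs coarse blocks 1007.1 (-54.0%)
```

Six superpixels recover the six planted regions exactly (adjusted Rand
index 1) and, despite using 6 segments against the 256 coarse blocks,
halve the cumulative series-reconstruction error: the blocks straddle
region boundaries, the superpixels do not.

A thin command-line wrapper covers generation, segmentation and assessment:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "stisebs.R", package = "stisebs"))') \
  run --input stack.tif --superpixels 500 --seed 42 --preprocess --out out/
```

## Scope

The package segments complete gridded index stacks in memory. Reprojection,
mosaicking, cloud masking beyond the NDVI range filter, Max-p
regionalization and hierarchical superpixel merging are out of scope.
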