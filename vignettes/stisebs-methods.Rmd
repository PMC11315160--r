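---
title: "Superpixels for spatial time series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superpixels for spatial time series: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stisebs)
```

## The problem

A dense vegetation-index archive — hundreds of 8-day periods over hundreds
of thousands of 250 m pixels — is too large for many downstream
environmental models, which forces analysts onto coarser grids and buries
subpixel heterogeneity inside every coarse cell. Superpixel segmentation
offers a middle path: partition the grid into contiguous groups of pixels
whose *whole time series* are similar, and replace each group by its mean
series. Done well, this loses far less temporal information than coarse
pixels of the same count, and — unlike SLIC-family methods, which can only
consume three feature channels — it can use the full temporal signal.

## The pipeline, stage by stage

**Preprocessing.** NDVI is `(NIR − Red)/(NIR + Red)`, with periods where
`NIR + Red = 0` treated as missing. Values outside `[-1, 1]` are *removed*
(not clamped) and handed to the gap filler, since out-of-range values are
sensor artefacts rather than extreme vegetation states. Gaps are filled by a
centered exponentially weighted moving average over ±3 periods, weights
`0.5^(|Δt|−1)` normalized over the available neighbours. A centered window
was chosen over a one-sided trailing window because NDVI series are strongly
seasonal and a one-sided filler would systematically lag the phase; the
decay base and half-width are configurable (`fill_gaps(window, decay)`).
A pixel whose gaps cannot be filled (no neighbour within the window) is
masked outright: the later stages need complete vectors, and partial series
would poison covariance estimates. Smoothing is Savitzky–Golay (default
window 7, quadratic), implemented as local least squares with the window
*shrunk* near the series ends rather than padded — padding would invent
observations at exactly the positions where the filter is least constrained.
An optional upper-envelope mode (`chen_iterations > 0`) iteratively replaces
points below the fitted curve by the fit and re-smooths, for users who want
the classic cloud-contamination-resistant envelope; it is off by default
because its iteration count is a data-dependent judgement call.

**Reduction.** PCA over pixels with periods as variables: center per period,
no standardization (all periods share NDVI units, so correlation-PCA would
artificially inflate low-variance periods). The covariance problem is solved
as a `T x T` eigenproblem via thin SVD (`prcomp`); the pixel-by-pixel Gram
matrix formulation has the same nonzero spectrum but is intractable when
pixels vastly outnumber periods. Retention keeps the smallest leading set
reaching `variance_target` (default 0.99), capped by `max_components`
(default 200, mirroring the case-study configuration). Two numerical
conventions make fits reproducible: eigenvector signs are fixed by making
each loading's largest-magnitude element positive, and the cumulative-ratio
comparison carries a `1e-12` slack so a spectrum that hits the target
exactly in real arithmetic is not rejected by floating-point rounding.
A constant input degenerates to a single zero-variance component with
explained ratio defined as 1.

**Clustering.** Seeded k-means on all retained components: k-means++
initialization, Lloyd iterations, convergence when the largest centroid
shift drops below `tol = 1e-4`, empty clusters re-seeded from the point
farthest from its centroid. The stage is deliberately non-spatial —
contiguity is restored afterwards — because adding coordinates here would
trade temporal fidelity for compactness twice (SLIC's weakness). k-means is
sensitive to initialization, so `run_stisebs()` defaults to five seeded
restarts (`n_start = 5`) and keeps the lowest objective; restart `s` uses
seed `seed + s − 1`, so the whole procedure remains a pure function of the
seed. A poor local optimum at this stage is unrecoverable downstream: if two
true regions land in one cluster and touch, they dissolve into a single
patch that SKATER can never split along the right boundary.

**Patches and SKATER.** Contiguity is rook (4-neighbour) throughout —
patches, adjacency, and the baselines — for consistency with
polygon-dissolve semantics; queen (8) is available behind the
`connectivity` flag. The patch graph's MST is built with Prim's algorithm
under a deterministic tie-break (lowest `(cost, min id, max id)`), and edge
ids are assigned in `(from, to)` order so that the pruning stage's
tie-break ("lowest edge id") is well defined. Pruning is greedy best-first:
every single-edge removal in every current tree is scored by the total
intracluster square deviation of the two resulting subtrees, and the global
best is committed. Candidate evaluation is exhaustive per tree, using one
preorder DFS with incremental subtree sums — not the heuristic candidate
expansion of the original SKATER formulation — because exactness makes the
step directly checkable against a brute-force oracle and costs only
`O(k · J · C)` at the scales this package targets.

Two objective variants are provided. The default scores a tree by the
*patch-count-normalized* deviation around the unweighted mean of patch
feature vectors, `SSD_k = (1/n_k) Σ ||x_j − x̄_k||²`; the alternative
(`weighted = TRUE`) is the classic pixel-count-weighted within-cluster sum
of squares. The normalized form treats patches as the unit objects of the
regionalization regardless of their pixel mass; the weighted form instead
penalizes by affected pixel count. Both are legitimate readings of the
method — the normalized form is the literal default, and the switch keeps
the other honest. Note a consequence of normalization: splitting a
homogeneous tree can *increase* the summed objective (two trees of the same
mean deviation sum to twice the parent's), so the greedy step is "least
harmful removal", not guaranteed descent.

**Assembly and assessment.** A superpixel's series is the unweighted mean
over member *pixels* (not patch means), so large patches contribute
proportionally. Assessment disassembles each segment back to its pixels,
assigns every pixel its segment's series, and accumulates per-pixel
Euclidean deviations (an L1 variant sits behind a flag; the per-pixel
aggregation over time is the L2 norm by default). Inhomogeneity δ is the
mean pairwise distance between member-pixel *series* — not component
scores, since the series is the quantity the reduction is supposed to
preserve — computed exactly up to a 2,000-pixel segment cap and by a seeded
unbiased 10,000-pair estimate (flagged) above it. Isolation γ uses segment
mean series and rook adjacency. Classification metrics are one-vs-rest
counts; overall accuracy is the confusion-matrix trace over the total, and
kappa is always computed from exact marginals (`a_l = TP + FN`,
`b_l = TP + FP`), never from a rounded accuracy, which matters because at
97–98 % accuracy the kappa is violently sensitive to the third decimal of
OA. Zero-denominator metrics report 0 with a `degenerate` flag rather than
NaN.

**Baselines.** Coarse blocks: non-overlapping `f × f` windows (default 4,
the 250 m → 1000 m ratio), partial edge blocks kept. e-SLIC: top three
principal components min-max scaled to `[0, 1]` per component, then SLIC
with combined distance `sqrt(d_feat² + (d_xy/S)² · m²)`, `S = sqrt(I/k)`,
ten iterations, grid-seeded centers, and a connectivity pass that keeps the
largest component per label and merges orphans into the most similar
adjacent segment. The compactness default `m = 0.3` with per-component
scaling was fixed once as a reasonable middle setting for unit-scaled
features; the benchmark formulation leaves its exact scaling unstated, so
both knobs are exposed.

## File formats

No GDAL-backed R raster package is assumed. The package ships a minimal
GeoTIFF codec: uncompressed, one band (page) per period, float64 samples
for series stacks (so round trips are bit-identical, with `NaN` as the
nodata sentinel) and int32 for label rasters (nodata −1), with
`ModelPixelScale`/`ModelTiepoint` tags for axis-aligned transforms and the
full transform, CRS string and period timestamps embedded as JSON in the
`ImageDescription` tag. The reader also accepts generic single-sample
uncompressed TIFFs (uint8/16, int16/32, float32/64). The suite cross-checks
written files against an independent TIFF reader. Reprojection and
compressed or tiled TIFFs are out of scope; timestamps degrade gracefully
to period indices because the algorithm only uses their order.

## The synthetic scene generator

`generate_scene()` emulates what the pipeline actually consumes: a seeded
mosaic of regions (Voronoi cells by default — convex, hence 4-connected),
each carrying a seasonal signature
`b + A sin(2πt/P + φ) + slope·t`, plus i.i.d. Gaussian noise (an AR(1)
option exists, since real NDVI noise is autocorrelated), missing
observations at a fixed rate, and optional localized additive dips standing
in for droughts or disturbance events. Default parameter ranges (base
0.05–0.45, amplitude 0.05–0.30, σ = 0.02, 2 % gaps, 46-step years) were
chosen once to resemble arid-rangeland NDVI at 8-day cadence and are not
tuned per experiment. The default test scene is 64 × 64 × 92 with six
regions — deliberately desk-scale (seconds, not the 30-hour region-scale
runs the method is ultimately aimed at).

What the generator does *not* emulate: mixed pixels along boundaries,
spatially correlated noise, cloud-contamination streaks, within-region
phenological gradients, and land-cover change over time. Tests that pass on
these scenes therefore demonstrate algorithmic correctness and the claimed
orderings under clean region structure, not performance on real MODIS
archives.

The anomaly scene family (`anomaly_scene_spec()`) probes the specific
argument for keeping the full component set: four distinct seasonal strips
occupy the top half (so the top three components are saturated by seasonal
contrasts), and the bottom half splits at an *off-center* column into two
regions whose signatures differ only by a mid-series dip of depth 0.15
(7.5 noise standard deviations). A three-component reduction cannot see the
dip, and the off-center boundary denies SLIC's spatial prior a lucky
symmetric split; a full-component segmentation has the dip direction
available. A perfectly regular layout would be solvable by the spatial
prior alone, which is why the boundary is placed off-center.

## Problem sizes and budgets

The test suite and the acceptance script run the full pipeline at
64 × 64 × 92 (recovery), 40 × 40 × 46 with 100 segments over 20 replicates
(comparative study), and 32 × 32 × 92 over 20 replicates (anomaly study);
oracle checks use matrices up to 20 × 20, graphs up to 12 nodes, and trees
up to 9 nodes with exhaustive enumeration. These sizes keep the whole suite
within a few minutes on one core while leaving every structural property
(partition, contiguity, counts, determinism) and every comparative ordering
exercised end to end.

## Known limitations

- The greedy SKATER step is exact per step but, like all greedy
  regionalization, carries no global optimality guarantee.
- k-means restarts reduce, but cannot eliminate, sensitivity to
  initialization; pathological cluster counts (k far above the number of
  distinguishable signatures) produce noise-driven patches whose MST
  pruning is correspondingly noise-driven.
- The equal-segment-count comparison on homogeneous synthetic scenes shows
  the two superpixel methods close in reconstruction error (the coarse
  blocks are clearly worse); the full-component advantage concentrates
  where the tail components carry structure, as in the anomaly scenes.
- δ above the exact-computation cap is a sampled estimate (flagged in the
  output); γ of a single-segment map is undefined and reported as `NA`.
- The GeoTIFF codec intentionally covers only the package's own profile
  plus plain uncompressed single-sample files.
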