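# End-to-end STiSeBS pipeline: (optional preprocessing) -> PCA -> k-means ->
# patch dissolution -> patch graph -> MST -> SKATER -> superpixel assembly.

#' Assemble per-segment mean series
#'
#' The series of a segment is the unweighted mean over its member pixels of
#' the (preprocessed) index series -- not a mean of patch means, so large and
#' small patches contribute by pixel count.
#'
#' @param segments a [label_grid()] whose labels are `0..k-1` on valid
#'   pixels.
#' @param grid the [ts_grid()] the segments live on.
#' @return an object of class `superpixel_set`: `labels` (the segment grid),
#'   `k`, `pixel_counts` (length k), `series` (`k x T` matrix of mean
#'   series), `times`.
#' @export
assemble_superpixels <- function(segments, grid) {
  stopifnot(inherits(segments, "label_grid"), inherits(grid, "ts_grid"))
  pm <- flatten(grid)
  seg <- segments$labels[pm$index]
  if (any(seg < 0L)) stop("valid pixel without a segment label")
  lev <- sort(unique(seg))
  sums <- rowsum(pm$data, seg, reorder = TRUE)
  cnt <- as.vector(table(factor(seg, levels = lev)))
  structure(list(labels = segments, k = length(lev), pixel_counts = cnt,
                 series = sums / cnt, times = grid$times),
            class = "superpixel_set")
}

#' @export
print.superpixel_set <- function(x, ...) {
  cat(sprintf("<superpixel_set> %d segments over %d pixels, T=%d\n",
              x$k, sum(x$pixel_counts), ncol(x$series)))
  invisible(x)
}

#' Run the full STiSeBS segmentation
#'
#' Chains the whole algorithm on a time-series grid: principal-component
#' reduction of the per-pixel series to a variance target, seeded k-means on
#' all retained components (non-spatial), dissolution of clusters into
#' contiguous patches, SKATER partitioning of the patch
#' minimum-spanning-tree into `k_superpixels` contiguous superpixels, and
#' assembly of per-superpixel mean series. Superpixel labels are compacted
#' in row-major first-occurrence order, so a fixed seed yields byte-identical
#' label rasters.
#'
#' @param stack a [ts_grid()]; set `preprocess = TRUE` to run
#'   [preprocess_stack()] first (range filter, gap fill, smoothing).
#' @param k_superpixels number of superpixels.
#' @param k_clusters number of k-means clusters; defaults to `k_superpixels`
#'   (the case-study configuration sets both to the LR pixel count).
#' @param variance_target,max_components see [fit_pca()].
#' @param seed integer seed driving k-means.
#' @param connectivity 4 (rook, default) or 8 for patches and adjacency.
#' @param weighted see [skater_partition()].
#' @param preprocess run the preprocessing chain first.
#' @param n_start k-means restarts (see [kmeans_cluster()]).
#' @return a list: `labels` (superpixel [label_grid()]), `superpixels`
#'   ([assemble_superpixels()] result, augmented with per-superpixel `ssd`
#'   and `n_patches`), and stage artifacts `pca`, `clusters`, `patches`,
#'   `graph`, `mst`, `skater`, `grid` (the grid actually segmented).
#' @export
run_stisebs <- function(stack, k_superpixels, k_clusters = k_superpixels,
                        variance_target = 0.99, max_components = 200L,
                        seed = 1L, connectivity = 4L, weighted = FALSE,
                        preprocess = FALSE, n_start = 5L) {
  stopifnot(inherits(stack, "ts_grid"))
  grid <- if (preprocess) preprocess_stack(stack) else stack
  pm <- flatten(grid)
  model <- fit_pca(pm, variance_target = variance_target,
                   max_components = max_components)
  scores <- pca_transform(model, pm$data)
  spm <- pm; spm$data <- scores
  cm <- kmeans_cluster(scores, k_clusters, seed = seed, n_start = n_start)
  clg <- cluster_label_grid(cm, pm)
  pt <- label_patches(clg, connectivity)
  J <- nrow(pt$table)
  if (k_superpixels > J)
    stop(sprintf("k_superpixels (%d) exceeds the number of patches (%d)",
                 k_superpixels, J))
  X <- patch_means(pt$labels, spm)
  g <- build_patch_graph(pt$labels, X, connectivity)
  mst <- minimum_spanning_tree(g)
  sk <- skater_partition(mst, X, k_superpixels, sizes = pt$table$size,
                         weighted = weighted)
  lab <- pt$labels$labels
  out <- lab
  out[lab >= 0L] <- sk$assignment[lab[lab >= 0L] + 1L]
  splg <- compact_labels(label_grid(out, "superpixel", grid$geometry))
  sp <- assemble_superpixels(splg, grid)
  # carry SKATER per-tree stats over to the compacted numbering
  remap <- integer(sp$k)
  pre <- out[splg$labels >= 0L]
  post <- splg$labels[splg$labels >= 0L]
  m <- !duplicated(post)
  remap[post[m] + 1L] <- pre[m] + 1L
  sp$ssd <- sk$ssd[remap]
  sp$n_patches <- sk$n_patches[remap]
  list(labels = splg, superpixels = sp, pca = model, clusters = cm,
       patches = pt, graph = g, mst = mst, skater = sk, grid = grid)
}
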