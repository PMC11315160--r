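# Patch dissolution: contiguous pixels sharing a k-means cluster label are
# grouped into patches, each patch receives the mean component vector of its
# member pixels, and patch adjacency becomes the graph that SKATER partitions.

# neighbour pixel pairs (linear indices into an H x W matrix) under rook or
# queen contiguity, restricted to pairs where both pixels satisfy `keep`
neighbor_pairs <- function(H, W, keep, connectivity = 4L) {
  idx <- matrix(seq_len(H * W), H, W)
  pairs <- rbind(
    cbind(as.vector(idx[-H, ]), as.vector(idx[-1, ])),   # vertical
    cbind(as.vector(idx[, -W]), as.vector(idx[, -1]))    # horizontal
  )
  if (connectivity == 8L) {
    pairs <- rbind(pairs,
      cbind(as.vector(idx[-H, -W]), as.vector(idx[-1, -1])),  # diag down-right
      cbind(as.vector(idx[-1, -W]), as.vector(idx[-H, -1])))  # diag up-right
  }
  pairs[keep[pairs[, 1]] & keep[pairs[, 2]], , drop = FALSE]
}

#' Dissolve a cluster map into contiguous patches
#'
#' Connected components are computed within each cluster label (rook
#' contiguity by default), then relabelled consecutively from 0 in row-major
#' first-occurrence order.
#'
#' @param clusters a [label_grid()] of kind `"cluster"` (any label grid
#'   works).
#' @param connectivity 4 (rook, default) or 8 (queen).
#' @return a list with `labels` (a [label_grid()] of kind `"patch"`) and
#'   `table` (data frame: `patch`, `cluster`, `size`), ordered by patch id.
#' @export
label_patches <- function(clusters, connectivity = 4L) {
  stopifnot(inherits(clusters, "label_grid"), connectivity %in% c(4L, 8L))
  lab <- clusters$labels
  valid <- lab >= 0L
  pr <- neighbor_pairs(nrow(lab), ncol(lab), valid, connectivity)
  pr <- pr[lab[pr[, 1]] == lab[pr[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(pr), ncol = 2), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(which(valid)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  out <- matrix(-1L, nrow(lab), ncol(lab))
  out[as.integer(names(comp))] <- as.integer(comp)
  plg <- compact_labels(label_grid(out, "patch", clusters$geometry))
  pid <- plg$labels[valid]
  ord <- !duplicated(pid)
  tab <- data.frame(patch = pid[ord], cluster = lab[valid][ord],
                    size = as.integer(table(factor(pid))[as.character(pid[ord])]))
  tab <- tab[order(tab$patch), , drop = FALSE]
  rownames(tab) <- NULL
  list(labels = plg, table = tab)
}

#' Mean component vector per patch
#'
#' The unweighted mean of the member pixels' score vectors.
#'
#' @param patch_labels a [label_grid()] of kind `"patch"` (labels `0..J-1`).
#' @param scores a component grid ([pca_transform()] output) or an aligned
#'   [flatten()] result of scores.
#' @return a `J x C` matrix; row `j + 1` is the mean vector of patch `j`.
#' @export
patch_means <- function(patch_labels, scores) {
  pm <- if (inherits(scores, "ts_grid")) flatten(scores) else scores
  stopifnot(inherits(pm, "pixel_matrix"))
  pid <- patch_labels$labels[pm$index]
  stopifnot(all(pid >= 0L))
  sums <- rowsum(pm$data, pid, reorder = TRUE)
  cnt <- as.vector(table(factor(pid, levels = sort(unique(pid)))))
  sums / cnt
}

#' Build the patch adjacency graph
#'
#' One node per patch; an edge for every pair of patches that share a
#' 4-neighbour (or 8-neighbour) pixel boundary; edge cost is the Euclidean
#' distance between the two patches' mean component vectors. Edges are
#' ordered by `(from, to)` with `from < to`, which defines their ids.
#'
#' @param patch_labels a [label_grid()] of kind `"patch"`.
#' @param features `J x C` matrix from [patch_means()].
#' @param connectivity 4 (default) or 8.
#' @return an object of class `patch_graph`: `n` (node count), `edges`
#'   (data frame `from`, `to`, `cost`, 0-based patch ids).
#' @export
build_patch_graph <- function(patch_labels, features, connectivity = 4L) {
  lab <- patch_labels$labels
  valid <- lab >= 0L
  pr <- neighbor_pairs(nrow(lab), ncol(lab), valid, connectivity)
  a <- lab[pr[, 1]]; b <- lab[pr[, 2]]
  keep <- a != b
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  key <- unique(cbind(lo, hi))
  key <- key[order(key[, 1], key[, 2]), , drop = FALSE]
  dif <- features[key[, 1] + 1L, , drop = FALSE] -
         features[key[, 2] + 1L, , drop = FALSE]
  edges <- data.frame(from = key[, 1], to = key[, 2],
                      cost = sqrt(rowSums(dif^2)))
  structure(list(n = nrow(features), edges = edges), class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}
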