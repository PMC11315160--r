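# Assessment: segment maps are disassembled back to their constituent
# high-resolution pixels, each pixel carrying its segment's mean series, and
# the reconstruction is scored against the true per-pixel series
# (time-series deviation, inhomogeneity/isolation) and against a categorical
# land-cover map (confusion-matrix metrics).

#' Broadcast segment mean series back to pixels
#'
#' Every valid pixel receives the mean series of the segment it belongs to --
#' the "hypothetical HR pixel" reconstruction used for assessment.
#'
#' @param sp a [assemble_superpixels()] result (or any list with `labels`
#'   and a `k x T` `series` matrix).
#' @return a [ts_grid()] of reconstructed series.
#' @export
broadcast_to_hr <- function(sp) {
  lg <- sp$labels
  lab <- lg$labels
  if (any(lab >= sp$k)) stop("segment label outside series table")
  H <- nrow(lab); W <- ncol(lab); Tn <- ncol(sp$series)
  vals <- array(NA_real_, c(H, W, Tn))
  valid <- lab >= 0L
  idx <- which(valid)
  seg <- lab[idx] + 1L
  for (t in seq_len(Tn))
    vals[idx + (t - 1L) * H * W] <- sp$series[seg, t]
  ts_grid(vals, times = sp$times, mask = valid, geometry = lg$geometry)
}

#' Time-series deviation between two stacks
#'
#' Per-pixel error is the Euclidean (L2) distance between the two series
#' over time; the cumulative error is the sum of per-pixel errors over all
#' valid pixels. An L1 variant (sum of absolute deviations per pixel) is
#' available.
#'
#' @param truth,estimate [ts_grid()]s on the same grid and mask.
#' @param norm `"l2"` (default) or `"l1"` per-pixel aggregation over time.
#' @return a list: `total` (cumulative error), `per_pixel` (vector over
#'   valid pixels, row-major order).
#' @export
euclidean_error <- function(truth, estimate, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  stopifnot(inherits(truth, "ts_grid"), inherits(estimate, "ts_grid"))
  if (!all(dim(truth$values) == dim(estimate$values)))
    stop("stacks have different shapes")
  if (!identical(truth$mask, estimate$mask))
    stop("stacks have different masks")
  pt <- flatten(truth); pe <- flatten(estimate)
  d <- pt$data - pe$data
  per <- if (norm == "l2") sqrt(rowSums(d^2)) else rowSums(abs(d))
  list(total = sum(per), per_pixel = per)
}

#' Inhomogeneity (delta) of a segmentation
#'
#' Per segment: the mean Euclidean distance between the index series of all
#' unordered member-pixel pairs (0 for singletons). Lower is better. For
#' segments larger than `max_exact` pixels an unbiased seeded random-pair
#' estimate with `n_pairs` draws is used and flagged.
#'
#' @param sp a [assemble_superpixels()] result.
#' @param grid the [ts_grid()] of true series.
#' @param max_exact exact-computation size cap (pairs are enumerated up to
#'   this segment size).
#' @param n_pairs sample size for the estimate above the cap.
#' @param seed seed for the sampled estimate.
#' @return a list: `per_segment` (delta per segment), `approximated`
#'   (logical per segment), `mean` (unweighted mean over segments),
#'   `weighted_mean` (pixel-count-weighted).
#' @export
inhomogeneity <- function(sp, grid, max_exact = 2000L, n_pairs = 10000L,
                          seed = 1L) {
  stopifnot(inherits(grid, "ts_grid"))
  pm <- flatten(grid)
  seg <- sp$labels$labels[pm$index]
  delta <- numeric(sp$k)
  approx_flag <- logical(sp$k)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  for (s in seq_len(sp$k)) {
    rows <- which(seg == s - 1L)
    m <- length(rows)
    if (m < 2L) { delta[s] <- 0; next }
    if (m <= max_exact) {
      delta[s] <- mean(stats::dist(pm$data[rows, , drop = FALSE]))
    } else {
      i <- sample.int(m, n_pairs, replace = TRUE)
      j <- sample.int(m - 1L, n_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)   # uniform over ordered distinct pairs
      d <- pm$data[rows[i], , drop = FALSE] - pm$data[rows[j], , drop = FALSE]
      delta[s] <- mean(sqrt(rowSums(d^2)))
      approx_flag[s] <- TRUE
    }
  }
  list(per_segment = delta, approximated = approx_flag,
       mean = mean(delta),
       weighted_mean = sum(delta * sp$pixel_counts) / sum(sp$pixel_counts))
}

#' Isolation (gamma) of a segmentation
#'
#' Per segment: the mean Euclidean distance between its mean series and the
#' mean series of its 4-adjacent segments. Higher is better. A segment with
#' no neighbour (single-segment map) gets `NA`.
#'
#' @param sp a [assemble_superpixels()] result.
#' @param connectivity 4 (default) or 8 for segment adjacency.
#' @return a list: `per_segment`, `mean` (over segments with neighbours),
#'   `weighted_mean` (pixel-count-weighted over the same segments).
#' @export
isolation <- function(sp, connectivity = 4L) {
  lab <- sp$labels$labels
  valid <- lab >= 0L
  pr <- neighbor_pairs(nrow(lab), ncol(lab), valid, connectivity)
  a <- lab[pr[, 1]]; b <- lab[pr[, 2]]
  keep <- a != b
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  adj <- unique(cbind(lo, hi))
  gamma <- rep(NA_real_, sp$k)
  if (nrow(adj)) {
    d <- sqrt(rowSums((sp$series[adj[, 1] + 1L, , drop = FALSE] -
                       sp$series[adj[, 2] + 1L, , drop = FALSE])^2))
    both <- c(adj[, 1], adj[, 2]) + 1L
    dd <- c(d, d)
    sums <- tapply(dd, both, sum)
    cnts <- tapply(dd, both, length)
    gamma[as.integer(names(sums))] <- sums / cnts
  }
  ok <- !is.na(gamma)
  list(per_segment = gamma, mean = mean(gamma[ok]),
       weighted_mean = if (any(ok))
         sum(gamma[ok] * sp$pixel_counts[ok]) / sum(sp$pixel_counts[ok])
       else NA_real_)
}

#' Majority land-cover label per segment
#'
#' Each segment is assigned its modal land-cover class (ties broken by the
#' smallest class id), and every member pixel receives that class -- the
#' predicted land-cover map used for classification accuracy.
#'
#' @param segments a segment [label_grid()].
#' @param landcover a [label_grid()] of kind `"landcover"` on the same
#'   geometry.
#' @return a predicted land-cover [label_grid()].
#' @export
majority_label <- function(segments, landcover) {
  stopifnot(inherits(segments, "label_grid"), inherits(landcover, "label_grid"))
  seg <- segments$labels; lc <- landcover$labels
  if (!all(dim(seg) == dim(lc))) stop("geometry mismatch")
  valid <- seg >= 0L & lc >= 0L
  tab <- table(seg[valid], lc[valid])
  classes <- as.integer(colnames(tab))
  # which.max returns the first maximum; columns are in ascending class
  # order, which implements the smallest-class-id tie-break
  modal <- classes[apply(tab, 1L, which.max)]
  names(modal) <- rownames(tab)
  out <- matrix(-1L, nrow(seg), ncol(seg))
  out[valid] <- modal[as.character(seg[valid])]
  label_grid(out, "landcover", segments$geometry)
}

#' Per-class confusion metrics from one-vs-rest counts
#'
#' @param tp,fp,fn,tn equal-length numeric vectors of one-vs-rest counts.
#' @return a data frame with the counts plus `precision`, `sensitivity`,
#'   `f1`, `mcc`, and a `degenerate` flag marking classes where a
#'   zero denominator forced a metric to 0.
#' @export
confusion_metrics_from_counts <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * sensitivity, precision + sensitivity)
  mden <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mden)
  degenerate <- (tp + fp) == 0 | (tp + fn) == 0 |
    (precision + sensitivity) == 0 | mden == 0
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
             sensitivity = sensitivity, f1 = f1, mcc = mcc,
             degenerate = degenerate)
}

#' Classification accuracy of a predicted class map
#'
#' One-vs-rest TP/FP/FN/TN per class, per-class precision, sensitivity, F1
#' and Matthews correlation, overall accuracy (confusion-matrix trace over
#' total), and the kappa coefficient computed from the exact actual/predicted
#' marginals `a_l = TP + FN`, `b_l = TP + FP`:
#' `kappa = (I^2 OA - sum(a_l b_l)) / (I^2 - sum(a_l b_l))`.
#'
#' @param truth,predicted [label_grid()]s on the same geometry; pixels
#'   masked in either are excluded.
#' @return an object of class `class_metrics`: `per_class` (data frame with
#'   a `class` column and the metric columns of
#'   [confusion_metrics_from_counts()]), `overall_accuracy`, `kappa`,
#'   `n_pixels`, `n_classes`.
#' @export
classification_metrics <- function(truth, predicted) {
  stopifnot(inherits(truth, "label_grid"), inherits(predicted, "label_grid"))
  tl <- truth$labels; pl <- predicted$labels
  if (!all(dim(tl) == dim(pl))) stop("geometry mismatch")
  valid <- tl >= 0L & pl >= 0L
  tv <- tl[valid]; pv <- pl[valid]
  classes <- sort(unique(c(tv, pv)))
  cm <- table(factor(tv, levels = classes), factor(pv, levels = classes))
  I <- sum(cm)
  tp <- diag(cm)
  a <- rowSums(cm)            # actual count per class
  b <- colSums(cm)            # predicted count per class
  fn <- a - tp
  fp <- b - tp
  tn <- I - tp - fn - fp
  per <- cbind(class = classes,
               confusion_metrics_from_counts(tp, fp, fn, tn))
  rownames(per) <- NULL
  oa <- sum(tp) / I
  kappa <- (I^2 * oa - sum(a * b)) / (I^2 - sum(a * b))
  structure(list(per_class = per, overall_accuracy = oa, kappa = kappa,
                 n_pixels = I, n_classes = length(classes)),
            class = "class_metrics")
}

#' Kappa coefficient from one-vs-rest table rows
#'
#' For published confusion tables that only list per-class TP/FP/FN counts,
#' the exact marginals are `a_l = TP + FN` and `b_l = TP + FP` and the
#' multi-class overall accuracy is `sum(TP) / I`.
#'
#' @param tp,fp,fn per-class counts.
#' @param n_pixels total pixel count I.
#' @return a list with `overall_accuracy` and `kappa`.
#' @export
kappa_from_marginals <- function(tp, fp, fn, n_pixels) {
  tp <- as.numeric(tp); fp <- as.numeric(fp); fn <- as.numeric(fn)
  n_pixels <- as.numeric(n_pixels)
  a <- tp + fn; b <- tp + fp
  oa <- sum(tp) / n_pixels
  list(overall_accuracy = oa,
       kappa = (n_pixels^2 * oa - sum(a * b)) / (n_pixels^2 - sum(a * b)))
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> %d classes over %s pixels: OA=%.4f, kappa=%.4f\n",
              x$n_classes, format(x$n_pixels, big.mark = ","),
              x$overall_accuracy, x$kappa))
  invisible(x)
}

#' Coarse-pixel (block aggregation) baseline
#'
#' Segments are non-overlapping `factor x factor` blocks -- the
#' low-resolution pixels a coarser sensor would deliver (a factor of 4 maps
#' a 250 m grid onto a 1000 m grid). Partial blocks at the right/bottom
#' edges are kept as smaller segments. Blocks with no valid pixel produce no
#' segment.
#'
#' @param stack a [ts_grid()].
#' @param factor block edge length in pixels, `>= 1`.
#' @return a list: `labels` (block [label_grid()]), `superpixels`
#'   ([assemble_superpixels()] result with block-mean series).
#' @export
coarse_pixel_baseline <- function(stack, factor = 4L) {
  stopifnot(inherits(stack, "ts_grid"), factor >= 1L)
  H <- stack$geometry$height; W <- stack$geometry$width
  br <- (seq_len(H) - 1L) %/% factor
  bc <- (seq_len(W) - 1L) %/% factor
  nbc <- max(bc) + 1L
  block <- outer(br, bc, function(r, c) r * nbc + c)
  block[!stack$mask] <- -1L
  lg <- compact_labels(label_grid(block, "superpixel", stack$geometry))
  list(labels = lg, superpixels = assemble_superpixels(lg, stack))
}
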