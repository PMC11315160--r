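test_that("broadcasting segment means back to pixels conserves the mean", {
  sc <- generate_scene(scene_spec(height = 8, width = 8, periods = 6,
                                  n_regions = 3, noise_sd = 0.05,
                                  gap_fraction = 0, seed = 3))
  lab <- compact_labels(label_grid(matrix(sample(0:3, 64, replace = TRUE),
                                          8, 8), "superpixel"))
  sp <- assemble_superpixels(lab, sc$grid)
  hr <- broadcast_to_hr(sp)
  # pixel-weighted mean of the broadcast equals the global mean series
  expect_equal(colMeans(flatten(hr)$data), colMeans(flatten(sc$grid)$data),
               tolerance = 1e-10)
  # one segment covering everything: every pixel gets the global mean
  one <- assemble_superpixels(label_grid(matrix(0L, 8, 8), "superpixel"),
                              sc$grid)
  hr1 <- broadcast_to_hr(one)
  expect_equal(hr1$values[3, 5, ], colMeans(flatten(sc$grid)$data),
               tolerance = 1e-10, ignore_attr = TRUE)
  # singleton superpixels: broadcast reproduces the original
  ident <- compact_labels(label_grid(matrix(0:63, 8, 8), "superpixel"))
  hri <- broadcast_to_hr(assemble_superpixels(ident, sc$grid))
  expect_equal(hri$values, sc$grid$values, tolerance = 1e-12)
})

test_that("time-series deviation matches term-by-term summation", {
  a <- make_grid(array(runif(3 * 1 * 4), c(3, 1, 4)))
  b <- make_grid(a$values + array(rnorm(12, 0, 0.1), c(3, 1, 4)))
  got <- euclidean_error(a, b)
  ref <- sum(sqrt(rowSums((flatten(a)$data - flatten(b)$data)^2)))
  expect_equal(got$total, ref, tolerance = 1e-12)
  # identical grids: zero
  expect_equal(euclidean_error(a, a)$total, 0)
  # single-coordinate difference of 0.3
  c2 <- a
  c2$values[2, 1, 3] <- c2$values[2, 1, 3] + 0.3
  expect_equal(euclidean_error(a, c2)$total, 0.3, tolerance = 1e-12)
  # L1 variant
  expect_equal(euclidean_error(a, c2, norm = "l1")$total, 0.3,
               tolerance = 1e-12)
})

test_that("segment-mean reconstruction minimizes summed squared deviation", {
  set.seed(10)
  sc <- generate_scene(scene_spec(height = 6, width = 6, periods = 8,
                                  n_regions = 2, noise_sd = 0.1,
                                  gap_fraction = 0, seed = 10))
  lab <- compact_labels(label_grid(matrix(sample(0:2, 36, replace = TRUE),
                                          6, 6), "superpixel"))
  sp <- assemble_superpixels(lab, sc$grid)
  base <- sum(euclidean_error(sc$grid, broadcast_to_hr(sp))$per_pixel^2)
  for (i in 1:5) {
    sp2 <- sp
    sp2$series <- sp$series + matrix(rnorm(length(sp$series), 0, 0.05),
                                     nrow(sp$series))
    pert <- sum(euclidean_error(sc$grid, broadcast_to_hr(sp2))$per_pixel^2)
    expect_gt(pert, base)
  }
})

test_that("inhomogeneity equals pairwise enumeration and scales correctly", {
  sc <- generate_scene(scene_spec(height = 5, width = 5, periods = 6,
                                  n_regions = 2, noise_sd = 0.08,
                                  gap_fraction = 0, seed = 5))
  pm <- flatten(sc$grid)
  # 5-pixel segment: brute force over all 10 pairs
  lab <- matrix(1L, 5, 5)
  lab[1, ] <- 0L
  lg <- compact_labels(label_grid(lab, "superpixel"))
  sp <- assemble_superpixels(lg, sc$grid)
  d <- inhomogeneity(sp, sc$grid)
  rows <- which(lg$labels[pm$index] == 0L)
  M <- pm$data[rows, ]
  ref <- mean(as.vector(stats::dist(M)))
  expect_equal(d$per_segment[1], ref, tolerance = 1e-12)
  # the one-segment map equals the mean pairwise distance of the image
  all1 <- assemble_superpixels(label_grid(matrix(0L, 5, 5), "superpixel"),
                               sc$grid)
  expect_equal(inhomogeneity(all1, sc$grid)$per_segment,
               mean(as.vector(stats::dist(pm$data))), tolerance = 1e-12)
  # singletons have zero inhomogeneity
  ident <- compact_labels(label_grid(matrix(0:24, 5, 5), "superpixel"))
  di <- inhomogeneity(assemble_superpixels(ident, sc$grid), sc$grid)
  expect_equal(di$per_segment, rep(0, 25))
  # sampled estimate stays near the exact value on a big segment
  ds <- inhomogeneity(all1, sc$grid, max_exact = 10L, n_pairs = 20000L,
                      seed = 2)
  expect_true(ds$approximated[1])
  expect_equal(ds$per_segment[1],
               mean(as.vector(stats::dist(pm$data))), tolerance = 0.05)
})

test_that("isolation equals a brute-force neighbour scan", {
  sc <- generate_scene(scene_spec(height = 6, width = 6, periods = 5,
                                  n_regions = 2, noise_sd = 0.05,
                                  gap_fraction = 0, seed = 7))
  # 2x2 mosaic of 3x3 blocks -> 4 segments
  lab <- outer((0:5) %/% 3, (0:5) %/% 3, function(r, c) r * 2L + c)
  lg <- compact_labels(label_grid(matrix(as.integer(lab), 6, 6),
                                  "superpixel"))
  sp <- assemble_superpixels(lg, sc$grid)
  iso <- isolation(sp)
  dmat <- as.matrix(stats::dist(sp$series))
  # rook adjacency of the mosaic: 0-1, 0-2, 1-3, 2-3 (no diagonals)
  expect_equal(iso$per_segment[1], mean(dmat[1, c(2, 3)]), tolerance = 1e-12)
  expect_equal(iso$per_segment[4], mean(dmat[4, c(2, 3)]), tolerance = 1e-12)
  # two identical-mean segments are not isolated at all
  v <- array(0.5, c(2, 2, 3))
  lg2 <- label_grid(matrix(c(0L, 0L, 1L, 1L), 2, 2), "superpixel")
  sp2 <- assemble_superpixels(lg2, make_grid(v))
  expect_equal(isolation(sp2)$per_segment, c(0, 0))
  # a single segment has no neighbours
  sp3 <- assemble_superpixels(label_grid(matrix(0L, 2, 2), "superpixel"),
                              make_grid(v))
  expect_true(is.na(isolation(sp3)$per_segment))
})

test_that("majority labelling is modal with deterministic ties", {
  seg <- label_grid(matrix(0L, 2, 4), "superpixel")
  lc <- label_grid(matrix(c(4L, 4L, 4L, 4L, 4L, 7L, 7L, 7L), 2, 4),
                   "landcover")
  expect_true(all(majority_label(seg, lc)$labels == 4L))   # 5 vs 3
  lc_tie <- label_grid(matrix(c(7L, 7L, 7L, 7L, 4L, 4L, 4L, 4L), 2, 4),
                       "landcover")
  expect_true(all(majority_label(seg, lc_tie)$labels == 4L))  # tie: lower id
  # homogeneous segment keeps its class
  lc_h <- label_grid(matrix(2L, 2, 4), "landcover")
  expect_true(all(majority_label(seg, lc_h)$labels == 2L))
})

test_that("classification metrics agree with an independent implementation", {
  set.seed(8)
  truth <- label_grid(matrix(sample(0:3, 400, replace = TRUE), 20, 20),
                      "landcover")
  pred_m <- truth$labels
  flip <- sample(400, 120)
  pred_m[flip] <- sample(0:3, 120, replace = TRUE)
  pred <- label_grid(pred_m, "landcover")
  got <- classification_metrics(truth, pred)
  ref <- e1071::classAgreement(table(truth$labels, pred$labels))
  expect_equal(got$overall_accuracy, ref$diag, tolerance = 1e-12)
  expect_equal(got$kappa, ref$kappa, tolerance = 1e-12)
  # row-sum invariant per class
  pc <- got$per_class
  expect_true(all(pc$tp + pc$fp + pc$fn + pc$tn == got$n_pixels))
  # perfect prediction
  perf <- classification_metrics(truth, truth)
  expect_equal(perf$overall_accuracy, 1)
  expect_equal(perf$kappa, 1)
  expect_equal(perf$per_class$mcc, rep(1, 4))
})

test_that("zero-denominator metrics report zero with a flag", {
  m <- confusion_metrics_from_counts(tp = 0, fp = 0, fn = 5, tn = 95)
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$mcc, 0)
  expect_true(m$degenerate)
})

test_that("coarse blocks aggregate exactly", {
  sc <- generate_scene(scene_spec(height = 8, width = 8, periods = 4,
                                  n_regions = 2, noise_sd = 0.05,
                                  gap_fraction = 0, seed = 11))
  cb <- coarse_pixel_baseline(sc$grid, 4L)
  expect_equal(cb$superpixels$k, 4L)
  expect_true(all(cb$superpixels$pixel_counts == 16L))
  # block mean of a constant block is the constant
  v <- array(0.25, c(4, 4, 2))
  cb2 <- coarse_pixel_baseline(make_grid(v), 4L)
  expect_equal(as.vector(cb2$superpixels$series), c(0.25, 0.25))
  # factor 1: identity segmentation
  cb1 <- coarse_pixel_baseline(sc$grid, 1L)
  expect_equal(cb1$superpixels$k, 64L)
  # partial edge blocks survive as smaller segments
  sc2 <- generate_scene(scene_spec(height = 5, width = 6, periods = 3,
                                   n_regions = 1, noise_sd = 0,
                                   gap_fraction = 0, seed = 1))
  cb3 <- coarse_pixel_baseline(sc2$grid, 4L)
  expect_equal(cb3$superpixels$k, 4L)
  expect_equal(sort(cb3$superpixels$pixel_counts), c(2L, 4L, 8L, 16L))
})
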