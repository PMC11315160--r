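test_that("patch dissolution handles the canonical small cases", {
  # constant map: one patch of 9 pixels
  p1 <- label_patches(label_grid(matrix(0L, 3, 3), "cluster"))
  expect_equal(nrow(p1$table), 1L)
  expect_equal(p1$table$size, 9L)
  # checkerboard 2x2 under rook contiguity: four patches
  p2 <- label_patches(label_grid(matrix(c(0L, 1L, 1L, 0L), 2, 2), "cluster"))
  expect_equal(nrow(p2$table), 4L)
  # same map under queen contiguity: diagonals connect, two patches
  p8 <- label_patches(label_grid(matrix(c(0L, 1L, 1L, 0L), 2, 2), "cluster"),
                      connectivity = 8L)
  expect_equal(nrow(p8$table), 2L)
})

test_that("patch labelling equals an independent flood fill", {
  for (seed in 1:4) {
    set.seed(seed)
    lab <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
    lab[sample(64, 5)] <- -1L
    for (conn in c(4L, 8L)) {
      got <- label_patches(label_grid(lab, "cluster"), conn)$labels$labels
      ref <- oracle_flood_fill(lab, conn)
      expect_true(same_partition(got[lab >= 0], ref[lab >= 0]))
      expect_identical(got[lab < 0], ref[lab < 0])  # both -1
    }
  }
})

test_that("patch means average member pixels and conserve mass", {
  sc <- generate_scene(scene_spec(height = 6, width = 6, periods = 5,
                                  n_regions = 2, noise_sd = 0.05,
                                  gap_fraction = 0, seed = 2))
  pm <- flatten(sc$grid)
  cl <- label_grid(matrix(sample(0:2, 36, replace = TRUE), 6, 6), "cluster")
  pt <- label_patches(cl)
  X <- patch_means(pt$labels, pm)
  # mass conservation: sum_j H_j x_j = sum_i x_i
  expect_equal(colSums(X * pt$table$size), colSums(pm$data),
               tolerance = 1e-10)
  # singleton patches carry their pixel's vector
  singles <- which(pt$table$size == 1L)
  for (j in singles) {
    px <- which(pt$labels$labels[pm$index] == pt$table$patch[j])
    expect_equal(X[j, ], pm$data[px, ], ignore_attr = TRUE)
  }
  # direct two-point arithmetic
  expect_equal(colMeans(rbind(c(1, 0), c(3, 0))), c(2, 0))
})

test_that("the patch graph matches an exhaustive neighbour-pair scan", {
  set.seed(6)
  lab <- matrix(sample(0:1, 49, replace = TRUE), 7, 7)
  pt <- label_patches(label_grid(lab, "cluster"))
  plab <- pt$labels$labels
  X <- matrix(rnorm(nrow(pt$table) * 3), ncol = 3)
  g <- build_patch_graph(pt$labels, X)
  # brute force: every 4-neighbour pixel pair
  ref <- list()
  H <- nrow(plab); W <- ncol(plab)
  for (r in 1:H) for (cc in 1:W) {
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 > H || c2 > W) next
      a <- plab[r, cc]; b <- plab[r2, c2]
      if (a != b) ref[[length(ref) + 1]] <- c(min(a, b), max(a, b))
    }
  }
  ref <- unique(do.call(rbind, ref))
  ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
  expect_equal(cbind(g$edges$from, g$edges$to), ref, ignore_attr = TRUE)
  expect_equal(g$edges$cost,
               sqrt(rowSums((X[ref[, 1] + 1, ] - X[ref[, 2] + 1, ])^2)))
  # zero cost iff identical features
  X2 <- X; X2[2, ] <- X2[1, ]
  g2 <- build_patch_graph(pt$labels, X2)
  z <- g2$edges$from == 0 & g2$edges$to == 1
  if (any(z)) expect_equal(g2$edges$cost[z], 0)
})

test_that("two side-by-side patches produce a single edge", {
  lab <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  pt <- label_patches(label_grid(lab, "cluster"))
  g <- build_patch_graph(pt$labels, matrix(c(0, 1), 2, 1))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$cost, 1)
})
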