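grid_from_series <- function(y) make_grid(array(y, c(1, 1, length(y))))
series_of <- function(g) as.vector(g$values[1, 1, ])

test_that("NDVI follows its defining ratio, with zero-denominator masking", {
  nir <- make_grid(array(c(0.5, 0.3, 0.4), c(1, 1, 3)))
  red <- make_grid(array(c(0.1, 0.3, 0.0), c(1, 1, 3)))
  nd <- compute_ndvi(nir, red)
  expect_equal(series_of(nd), c(0.4 / 0.6, 0, 1))
  # NIR + Red = 0 becomes missing
  nir0 <- make_grid(array(c(0, 0.2), c(1, 1, 2)))
  red0 <- make_grid(array(c(0, 0.1), c(1, 1, 2)))
  expect_true(is.na(compute_ndvi(nir0, red0)$values[1, 1, 1]))
  # geometry mismatch rejected
  expect_error(compute_ndvi(nir, make_grid(array(0.1, c(1, 2, 3)))))
})

test_that("range filtering removes (not clamps) out-of-range values", {
  g <- grid_from_series(c(0.2, 1.7, 0.3))
  out <- clip_valid_range(g)
  expect_equal(series_of(out), c(0.2, NA, 0.3))
  g2 <- grid_from_series(c(-1, 0.5, 1))   # closed interval: endpoints kept
  expect_equal(series_of(clip_valid_range(g2)), c(-1, 0.5, 1))
})

test_that("gap filling uses normalized exponential weights over the window", {
  # symmetric neighbours at distance 1: plain average
  expect_equal(series_of(fill_gaps(grid_from_series(c(0.2, NA, 0.4)))),
               c(0.2, 0.3, 0.4))
  # constant neighbourhood
  expect_equal(series_of(fill_gaps(grid_from_series(c(NA, 0.2, 0.2, 0.2)))),
               rep(0.2, 4))
  # asymmetric weights: neighbours at distances 1 and 2 on one side, 1 on other
  got <- series_of(fill_gaps(grid_from_series(c(0.0, 0.1, NA, 0.4))))
  # neighbours of the gap: t-2 (w 0.5, 0.0), t-1 (w 1, 0.1), t+1 (w 1, 0.4)
  expect_equal(got[3], (0.5 * 0.0 + 1 * 0.1 + 1 * 0.4) / 2.5)
  # no gaps: identity
  y0 <- c(0.2, 0.3, 0.25, 0.4)
  expect_equal(series_of(fill_gaps(grid_from_series(y0))), y0)
  # unfillable gap masks the pixel
  long <- c(0.2, rep(NA, 7), 0.3, rep(NA, 1), 0.1)
  gf <- fill_gaps(grid_from_series(long))
  expect_false(gf$mask[1, 1])
})

test_that("Savitzky-Golay reproduces constants and linear ramps exactly", {
  cst <- rep(0.4, 20)
  expect_equal(series_of(smooth_savitzky_golay(grid_from_series(cst))), cst)
  ramp <- seq(-0.5, 0.5, length.out = 20)
  got <- series_of(smooth_savitzky_golay(grid_from_series(ramp),
                                         window = 7, order = 2))
  expect_equal(got, ramp, tolerance = 1e-12)   # incl. shrunk end windows
})

test_that("Savitzky-Golay equals local least-squares regression", {
  set.seed(3)
  y <- 0.3 + 0.2 * sin(seq_len(15) / 2) + rnorm(15, 0, 0.05)
  got <- series_of(smooth_savitzky_golay(grid_from_series(y),
                                         window = 7, order = 2))
  expect_equal(got, oracle_sg(y, 7, 2), tolerance = 1e-10)
  # interior points agree with the signal package's classic filter
  ref <- signal::sgolayfilt(y, p = 2, n = 7)
  expect_equal(got[4:12], ref[4:12], tolerance = 1e-10)
  expect_error(smooth_savitzky_golay(grid_from_series(y), window = 17),
               "window")
})

test_that("upper-envelope iterations never drop below plain smoothing", {
  set.seed(4)
  y <- pmax(pmin(0.3 + 0.25 * sin(seq_len(40) / 3) + rnorm(40, 0, 0.04),
                 1), -1)
  g <- grid_from_series(y)
  plain <- series_of(smooth_savitzky_golay(g, chen_iterations = 0))
  env <- series_of(smooth_savitzky_golay(g, chen_iterations = 3))
  expect_true(all(env >= plain - 1e-12))
  expect_true(all(env <= 1) && all(env >= -1))
})

test_that("the full chain yields complete in-range series on valid pixels", {
  sc <- generate_scene(scene_spec(height = 10, width = 10, periods = 46,
                                  n_regions = 3, noise_sd = 0.05,
                                  gap_fraction = 0.05, seed = 8))
  out <- preprocess_stack(sc$grid)
  pm <- flatten(out)
  expect_false(anyNA(pm$data))
  expect_true(all(pm$data >= -1 & pm$data <= 1))
})
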