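# Small fixture builders shared across test files.

# ts_grid from an (H, W, T) array with optional mask
make_grid <- function(values, mask = NULL, times = NULL) {
  ts_grid(values, times = times, mask = mask)
}

# two-rectangle zero-noise scene: left half signature a(t), right half b(t)
two_region_grid <- function(H = 10L, W = 10L, Tn = 12L) {
  t <- seq_len(Tn)
  a <- 0.2 + 0.1 * sin(2 * pi * t / Tn)
  b <- 0.6 + 0.2 * sin(2 * pi * t / Tn + 1)
  vals <- array(0, c(H, W, Tn))
  for (tt in t) {
    vals[, seq_len(W %/% 2), tt] <- a[tt]
    vals[, (W %/% 2 + 1):W, tt] <- b[tt]
  }
  truth <- matrix(rep(c(0L, 1L), c(W %/% 2, W - W %/% 2)),
                  H, W, byrow = TRUE)
  list(grid = make_grid(vals), truth = label_grid(truth, "landcover"))
}

# well-separated Gaussian blobs in C dims; returns scores and membership
two_blob_scores <- function(n_per = 30L, C = 4L, dist = 20, sd = 0.5,
                            seed = 42L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * C, 0, sd), n_per, C),
             matrix(stats::rnorm(n_per * C, dist, sd), n_per, C))
  list(X = X, membership = rep(0:1, each = n_per))
}

# pixel-count-weighted replicate study scene (desk scale)
study_scene <- function(seed) {
  generate_scene(scene_spec(height = 40L, width = 40L, periods = 46L,
                            seed = seed))
}
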