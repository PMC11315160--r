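# data whose sample covariance is exactly a given diagonal spectrum
spectrum_data <- function(lambda) {
  n <- length(lambda) + 1L
  Q <- qr.Q(qr(cbind(1, stats::contr.helmert(n))))[, -1, drop = FALSE]
  sqrt(n - 1) * Q %*% diag(sqrt(lambda))
}

test_that("rank-1 data yields a single component explaining everything", {
  X <- outer(seq(0.1, 1, length.out = 10), c(1, 2, 3))
  m <- fit_pca(X)
  expect_equal(m$n_components, 1L)
  expect_equal(sum(m$explained_ratio), 1, tolerance = 1e-12)
})

test_that("component retention hits an exact cumulative variance boundary", {
  X <- spectrum_data(c(8, 1.5, 0.4, 0.08, 0.02))
  m <- fit_pca(X, variance_target = 0.99)
  expect_equal(m$eigenvalues, c(8, 1.5, 0.4, 0.08, 0.02), tolerance = 1e-10)
  expect_equal(m$n_components, 3L)   # 8 + 1.5 + 0.4 = 99% of 10 exactly
  expect_equal(sum(m$explained_ratio), 0.99, tolerance = 1e-10)
  # the cap wins when tighter than the target
  expect_equal(fit_pca(X, 0.99, max_components = 2)$n_components, 2L)
})

test_that("PCA agrees with a brute-force covariance eigendecomposition", {
  for (seed in 1:5) {
    set.seed(seed)
    I <- sample(8:20, 1); Tn <- sample(3:20, 1)
    X <- matrix(rnorm(I * Tn), I, Tn) %*% diag(exp(seq(0, 2,
                                                       length.out = Tn)))
    m <- fit_pca(X, variance_target = 1, max_components = NULL)
    eig <- eigen(stats::cov(X), symmetric = TRUE)
    r <- min(I - 1, Tn)
    expect_equal(m$eigenvalues[1:r], eig$values[1:r], tolerance = 1e-8)
    for (j in seq_len(m$n_components)) {
      if (m$eigenvalues[j] < 1e-10) next
      expect_equal(abs(sum(m$loadings[, j] * eig$vectors[, j])), 1,
                   tolerance = 1e-6)
    }
    expect_true(all(diff(m$eigenvalues) <= 1e-10))
    # orthonormal loadings
    expect_equal(crossprod(m$loadings),
                 diag(m$n_components), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("full-rank reconstruction and score identities hold", {
  set.seed(7)
  X <- matrix(rnorm(30 * 6), 30, 6)
  m <- fit_pca(X, variance_target = 1, max_components = NULL)
  S <- pca_transform(m, X)
  # reconstruction from all components
  Xhat <- sweep(S %*% t(m$loadings), 2L, -m$center)
  expect_equal(Xhat, X, tolerance = 1e-10)
  # the mean series maps to the origin
  expect_equal(as.vector(pca_transform(m, matrix(m$center, 1))),
               rep(0, m$n_components), tolerance = 1e-10)
  # mean + 2 * first loading -> scores (2, 0, ..., 0)
  probe <- matrix(m$center + 2 * m$loadings[, 1], 1)
  expect_equal(as.vector(pca_transform(m, probe)),
               c(2, rep(0, m$n_components - 1)), tolerance = 1e-10)
  # per-component score variance equals the eigenvalue
  expect_equal(colSums(S^2) / (nrow(X) - 1),
               m$eigenvalues[seq_len(m$n_components)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("projection preserves distances fully and contracts truncated", {
  set.seed(11)
  X <- matrix(rnorm(15 * 8), 15, 8)
  full <- pca_transform(fit_pca(X, 1, NULL), X)
  part <- pca_transform(fit_pca(X, 0.6, NULL), X)
  d0 <- stats::dist(X); df <- stats::dist(full); dp <- stats::dist(part)
  expect_equal(as.vector(df), as.vector(d0), tolerance = 1e-10)
  expect_true(all(as.vector(dp) <= as.vector(d0) + 1e-10))
})

test_that("degenerate constant input reports one zero-variance component", {
  X <- matrix(0.5, 10, 4)
  m <- fit_pca(X)
  expect_equal(m$n_components, 1L)
  expect_equal(m$explained_ratio, 1)
  expect_equal(m$total_variance, 0)
})

test_that("incomplete series are rejected with guidance", {
  X <- matrix(rnorm(20), 5, 4); X[2, 3] <- NA
  expect_error(fit_pca(X), "fill_gaps")
})
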