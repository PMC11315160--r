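# Principal-component reduction of per-pixel time series. The covariance is
# taken over pixels (observations) with periods as variables -- a T x T
# eigenproblem solved through the thin SVD of the centered pixel matrix, which
# shares its nonzero spectrum with the pixel-by-pixel Gram formulation and is
# tractable in both the I >> T and T >> I regimes.

#' Fit a PCA model on a pixel matrix
#'
#' Centers each period (no standardization: all periods share index units)
#' and retains the smallest number of leading components whose cumulative
#' explained-variance ratio reaches `variance_target`, capped by
#' `max_components`. Eigenvector signs are fixed by making each loading's
#' largest-magnitude element positive, so fits are deterministic.
#'
#' @param x a [flatten()] result or a plain `I x T` numeric matrix (rows =
#'   pixels, columns = periods), `I >= 2`.
#' @param variance_target fraction of total variance to explain, in (0, 1].
#' @param max_components optional cap on the number of retained components
#'   (the case-study configuration caps at 200).
#' @return an object of class `pca_model` with fields `loadings` (`T x C`,
#'   orthonormal columns), `eigenvalues` (all `min(I-1, T)` sample-covariance
#'   eigenvalues, descending), `center` (per-period mean), `explained_ratio`
#'   (per-component fraction of total variance), `n_components`,
#'   `variance_target`, `total_variance`.
#' @export
fit_pca <- function(x, variance_target = 0.99, max_components = 200L) {
  X <- if (inherits(x, "pixel_matrix")) x$data else as.matrix(x)
  stopifnot(nrow(X) >= 2L, variance_target > 0, variance_target <= 1)
  if (anyNA(X))
    stop("series contain missing values; run fill_gaps / preprocess_stack first")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  total <- sum(lambda)
  if (total <= 0) {
    # constant matrix: a single zero-variance component, ratio defined as 1
    W <- pc$rotation[, 1L, drop = FALSE]
    return(structure(list(loadings = W, eigenvalues = lambda,
                          center = pc$center, explained_ratio = 1,
                          n_components = 1L,
                          variance_target = variance_target,
                          total_variance = 0),
                     class = "pca_model"))
  }
  ratio <- lambda / total
  cum <- cumsum(ratio)
  # tolerance so a cumulative ratio that equals the target in exact
  # arithmetic (e.g. 0.99) is not rejected on floating-point rounding
  C <- which(cum >= variance_target - 1e-12)[1L]
  if (is.na(C)) C <- length(lambda)
  if (!is.null(max_components)) C <- min(C, as.integer(max_components))
  W <- pc$rotation[, seq_len(C), drop = FALSE]
  for (j in seq_len(C)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(loadings = W, eigenvalues = lambda, center = pc$center,
                 explained_ratio = ratio[seq_len(C)], n_components = C,
                 variance_target = variance_target, total_variance = total),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> %d -> %d components (%.2f%% of variance, target %.0f%%)\n",
    nrow(x$loadings), x$n_components, 100 * sum(x$explained_ratio),
    100 * x$variance_target))
  invisible(x)
}

#' Project series onto the retained components
#'
#' Scores are the centered series projected on the loadings; masked pixels
#' stay `NA`.
#'
#' @param model a [fit_pca()] result.
#' @param x a [ts_grid()], a [flatten()] result, or an `I x T` matrix fitted
#'   with the same T.
#' @return for a grid input, a `ts_grid`-shaped component grid (`H x W x C`
#'   array of scores, mask preserved); for matrix-like input, the `I x C`
#'   score matrix.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(x, "ts_grid")) {
    pm <- flatten(x)
    scores <- pca_transform(model, pm$data)
    return(unflatten(pm, scores))
  }
  X <- if (inherits(x, "pixel_matrix")) x$data else as.matrix(x)
  if (ncol(X) != nrow(model$loadings))
    stop(sprintf("series length %d does not match model (%d periods)",
                 ncol(X), nrow(model$loadings)))
  sweep(X, 2L, model$center) %*% model$loadings
}
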