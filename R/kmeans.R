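# Seeded k-means (k-means++ initialization, Lloyd iterations) on component
# scores. The stage is deliberately non-spatial: superpixel contiguity is
# recovered later by patch dissolution and SKATER, so clustering here uses all
# retained components and no pixel coordinates.

# squared Euclidean distances between rows of X (n x d) and rows of C (k x d)
sqdist_xc <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- sqdist_xc(X, X[centers[1L], , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, sqdist_xc(X, X[centers[j + 1L], , drop = FALSE])[, 1L])
  }
  X[centers, , drop = FALSE]
}

#' k-means clustering of pixel scores
#'
#' k-means++ initialization followed by Lloyd iterations, both driven by the
#' given seed, so runs are reproducible. Iterations stop when every centroid
#' moves less than `tol` (Euclidean) or after `max_iter` rounds. Clusters
#' that empty out are re-seeded from the point farthest from its current
#' centroid. The within-cluster sum of squared distances is non-increasing
#' across iterations.
#'
#' @param scores an `I x C` score matrix, a [flatten()]-style object, or a
#'   component grid from [pca_transform()].
#' @param k number of clusters, `1 <= k <= I`.
#' @param seed integer seed for initialization and repair draws.
#' @param max_iter maximum Lloyd iterations.
#' @param tol convergence threshold on the largest centroid shift.
#' @param n_start number of independent seeded restarts; the run with the
#'   lowest objective wins (ties to the earliest restart). Restart `s` uses
#'   seed `seed + s - 1`.
#' @return an object of class `cluster_model`: `centroids` (`k x C`),
#'   `assignment` (length-I integer vector, values `0..k-1`), `objective`
#'   (final within-cluster sum of squared distances), `objective_trace`,
#'   `iterations`, `k`, `seed`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1L, max_iter = 300L,
                           tol = 1e-4, n_start = 1L) {
  X <- if (inherits(scores, "ts_grid")) flatten(scores)$data
       else if (inherits(scores, "pixel_matrix")) scores$data
       else as.matrix(scores)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and the number of pixels")
  if (n_start > 1L) {
    runs <- lapply(seq_len(n_start) - 1L, function(s)
      kmeans_cluster(X, k, seed = seed + s, max_iter = max_iter, tol = tol))
    best <- which.min(vapply(runs, `[[`, numeric(1), "objective"))
    out <- runs[[best]]
    out$seed <- seed
    out$n_start <- as.integer(n_start)
    return(out)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  C <- kmeanspp_init(X, k)
  trace <- numeric(0)
  assign_idx <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_xc(X, C)
    assign_idx <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(n), assign_idx)])
    trace <- c(trace, obj)
    newC <- C
    counts <- tabulate(assign_idx, nbins = k)
    if (any(counts == 0L)) {
      # farthest-point reseeding for empty clusters
      dmin <- d2[cbind(seq_len(n), assign_idx)]
      for (j in which(counts == 0L)) {
        far <- which.max(dmin)
        assign_idx[far] <- j
        dmin[far] <- 0
        counts <- tabulate(assign_idx, nbins = k)
      }
    }
    sums <- rowsum(X, assign_idx, reorder = TRUE)
    newC[sort(unique(assign_idx)), ] <- sums / counts[counts > 0L]
    shift <- sqrt(max(rowSums((newC - C)^2)))
    C <- newC
    if (shift < tol) break
  }
  d2 <- sqdist_xc(X, C)
  assign_idx <- max.col(-d2, ties.method = "first")
  obj <- sum(d2[cbind(seq_len(n), assign_idx)])
  structure(list(centroids = C, assignment = assign_idx - 1L,
                 objective = obj, objective_trace = trace,
                 iterations = it, k = k, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, objective=%.4g, %d iterations\n",
              x$k, x$objective, x$iterations))
  invisible(x)
}

#' Cluster assignment as a label grid
#'
#' @param model a [kmeans_cluster()] result.
#' @param pm the [flatten()] result the model was fitted on (provides the
#'   ordinal-to-(row, col) index map).
#' @return a [label_grid()] of kind `"cluster"`.
#' @export
cluster_label_grid <- function(model, pm) {
  lab <- matrix(-1L, pm$geometry$height, pm$geometry$width)
  lab[pm$index] <- model$assignment
  label_grid(lab, "cluster", pm$geometry)
}
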