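#' Grid geometry
#'
#' Describes the raster frame shared by all grids in a workflow: pixel counts,
#' the affine geotransform mapping (col, row) pixel indices to map coordinates,
#' a coordinate-reference identifier, and the nodata sentinel. Indexing is
#' 0-based (row, col), row-major; the transform follows the standard raster
#' convention (anchored at the outer corner of pixel (0, 0), half-open pixels):
#' `x = gt[1] + col*gt[2] + row*gt[3]`, `y = gt[4] + col*gt[5] + row*gt[6]`.
#'
#' @param height,width pixel counts, each >= 1.
#' @param transform numeric length-6 geotransform. Default places the origin at
#'   (0, 0) with unit pixels and north-up orientation.
#' @param crs coordinate-reference identifier, kept as an opaque string.
#' @param nodata nodata sentinel used when rasters are written to disk.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(height, width,
                          transform = c(0, 1, 0, 0, 0, -1),
                          crs = "", nodata = NaN) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(length(height) == 1L, length(width) == 1L,
            height >= 1L, width >= 1L, length(transform) == 6L)
  # invertibility: the 2x2 linear part must be non-singular
  det <- transform[2] * transform[6] - transform[3] * transform[5]
  if (!is.finite(det) || det == 0)
    stop("geotransform is not invertible (zero pixel area)")
  structure(list(height = height, width = width,
                 transform = as.numeric(transform),
                 crs = as.character(crs), nodata = nodata),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d, crs='%s'\n", x$height, x$width, x$crs))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  a$height == b$height && a$width == b$width &&
    all(abs(a$transform - b$transform) < tol)
}

#' Gridded time series
#'
#' The central data container: an `height x width x T` array of index values
#' (e.g. NDVI) with a validity mask. A pixel is valid only when it carries a
#' finite value in every period; pixels with remaining gaps after gap filling
#' stay masked and never enter downstream computations.
#'
#' @param values numeric array indexed `(row, col, t)`.
#' @param times optional character vector of length T (ISO-8601 dates). The
#'   algorithms only use their order, so `NULL` degrades to period indices.
#' @param mask optional logical `height x width` matrix; `TRUE` marks pixels
#'   that participate. Defaults to pixels with at least one finite
#'   observation: within-series gaps are data for [fill_gaps()], not nodata.
#'   [fill_gaps()] masks pixels whose gaps cannot be filled.
#' @param geometry a [grid_geometry()]; defaults to a unit grid.
#' @return an object of class `ts_grid` with fields `values`, `times`, `mask`,
#'   `geometry`.
#' @export
ts_grid <- function(values, times = NULL, mask = NULL, geometry = NULL) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3L)
  d <- dim(values)
  if (is.null(geometry)) geometry <- grid_geometry(d[1], d[2])
  stopifnot(geometry$height == d[1], geometry$width == d[2])
  if (!is.null(times)) {
    times <- as.character(times)
    stopifnot(length(times) == d[3])
    if (is.unsorted(times, strictly = TRUE))
      stop("times must be strictly increasing")
  }
  if (is.null(mask)) {
    # a pixel participates unless it carries no observation at all;
    # within-series gaps are data to be gap-filled, not nodata
    mask <- apply(is.finite(values), c(1, 2), any)
  } else {
    stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  }
  structure(list(values = values, times = times, mask = mask,
                 geometry = geometry),
            class = "ts_grid")
}

#' @export
print.ts_grid <- function(x, ...) {
  cat(sprintf("<ts_grid> %d x %d x %d, %d valid pixels\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$mask)))
  invisible(x)
}

n_periods <- function(grid) dim(grid$values)[3]

#' Integer label raster
#'
#' Segment labels over a grid: a k-means cluster map, a patch map, a
#' superpixel map, or a land-cover map. Valid pixels carry labels that are
#' consecutive integers starting at 0 after [compact_labels()]; masked pixels
#' carry -1.
#'
#' @param labels integer `height x width` matrix; `-1` (or `NA`, normalised to
#'   `-1`) marks masked pixels.
#' @param kind one of `"cluster"`, `"patch"`, `"superpixel"`, `"landcover"`.
#' @param geometry a [grid_geometry()]; defaults to a unit grid.
#' @return an object of class `label_grid`.
#' @export
label_grid <- function(labels, kind = c("cluster", "patch", "superpixel",
                                        "landcover"),
                       geometry = NULL) {
  kind <- match.arg(kind)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  labels[is.na(labels)] <- -1L
  if (is.null(geometry)) geometry <- grid_geometry(nrow(labels), ncol(labels))
  stopifnot(geometry$height == nrow(labels), geometry$width == ncol(labels))
  structure(list(labels = labels, kind = kind, geometry = geometry),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  lab <- x$labels[x$labels >= 0L]
  cat(sprintf("<label_grid:%s> %d x %d, %d segments\n", x$kind,
              nrow(x$labels), ncol(x$labels), length(unique(lab))))
  invisible(x)
}

#' Relabel segments as consecutive integers from 0
#'
#' Labels are reassigned in order of first occurrence in row-major scan order,
#' which makes label maps deterministic and comparable across runs.
#'
#' @param lg a [label_grid()].
#' @return a `label_grid` with labels `0..n_segments-1` on valid pixels.
#' @export
compact_labels <- function(lg) {
  lab <- lg$labels
  valid <- lab >= 0L
  # row-major scan order of a column-major R matrix
  ord <- order(row(lab)[valid], col(lab)[valid])
  v <- lab[valid][ord]
  first <- v[!duplicated(v)]
  new <- match(lab[valid][ord], first) - 1L
  out <- lab
  out[valid][ord] <- new
  label_grid(out, lg$kind, lg$geometry)
}

#' Flatten a grid to a valid-pixel matrix
#'
#' Produces the `I x T` matrix view used by PCA and clustering: one row per
#' valid pixel in row-major order, with a bidirectional index map back to
#' (row, col). `unflatten()` is the exact inverse on valid pixels.
#'
#' @param grid a [ts_grid()].
#' @return an object of class `pixel_matrix`: `data` (`I x T`), `index`
#'   (`I x 2` integer matrix of 1-based (row, col)), `mask`, `geometry`,
#'   `times`.
#' @export
flatten <- function(grid) {
  stopifnot(inherits(grid, "ts_grid"))
  mask <- grid$mask
  if (!any(mask)) stop("grid has no valid pixels")
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  ord <- order(rows, cols)           # row-major ordinals
  rows <- rows[ord]; cols <- cols[ord]
  Tn <- n_periods(grid)
  dat <- matrix(grid$values[cbind(rep(rows, Tn), rep(cols, Tn),
                                  rep(seq_len(Tn), each = length(rows)))],
                nrow = length(rows), ncol = Tn)
  structure(list(data = dat, index = cbind(row = rows, col = cols),
                 mask = mask, geometry = grid$geometry, times = grid$times),
            class = "pixel_matrix")
}

#' Rebuild a grid from a valid-pixel matrix
#'
#' @param pm a [flatten()] result (its index map and mask are reused).
#' @param data optional replacement `I x T'` matrix (e.g. component scores);
#'   defaults to `pm$data`.
#' @return a [ts_grid()] with `NA` outside the mask.
#' @export
unflatten <- function(pm, data = NULL) {
  stopifnot(inherits(pm, "pixel_matrix"))
  if (is.null(data)) data <- pm$data
  data <- as.matrix(data)
  stopifnot(nrow(data) == nrow(pm$index))
  H <- pm$geometry$height; W <- pm$geometry$width; Tn <- ncol(data)
  vals <- array(NA_real_, c(H, W, Tn))
  vals[cbind(rep(pm$index[, 1], Tn), rep(pm$index[, 2], Tn),
             rep(seq_len(Tn), each = nrow(data)))] <- as.numeric(data)
  tms <- if (!is.null(pm$times) && length(pm$times) == Tn) pm$times else NULL
  ts_grid(vals, times = tms, mask = pm$mask, geometry = pm$geometry)
}

#' Per-pixel series of one valid pixel by flat ordinal
#' @noRd
pixel_series <- function(grid, r, c) grid$values[r, c, ]

#' Extract label vector aligned with a pixel matrix's ordinals
#' @noRd
labels_for <- function(lg, pm) lg$labels[pm$index]
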