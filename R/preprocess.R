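# NDVI preprocessing: index computation, range filtering, gap filling and
# Savitzky-Golay smoothing applied per pixel over the time dimension.

#' Compute NDVI from NIR and Red reflectance stacks
#'
#' `NDVI = (NIR - Red) / (NIR + Red)` per pixel and period. Periods where
#' `NIR + Red = 0` become missing (to be gap-filled).
#'
#' @param nir,red [ts_grid()]s sharing geometry, times and mask.
#' @return a [ts_grid()] of NDVI values.
#' @export
compute_ndvi <- function(nir, red) {
  stopifnot(inherits(nir, "ts_grid"), inherits(red, "ts_grid"))
  if (!same_geometry(nir$geometry, red$geometry) ||
      n_periods(nir) != n_periods(red) || !identical(nir$times, red$times))
    stop("NIR and Red stacks do not share geometry and times")
  den <- nir$values + red$values
  out <- (nir$values - red$values) / den
  out[den == 0] <- NA_real_
  mask <- nir$mask & red$mask
  structure(list(values = out, times = nir$times, mask = mask,
                 geometry = nir$geometry), class = "ts_grid")
}

#' Remove index values outside the valid range
#'
#' Values outside `[-1, 1]` are removed (set missing, to be gap-filled), not
#' clamped; the interval is closed, so -1 and 1 are kept.
#'
#' @param grid a [ts_grid()].
#' @param lower,upper closed range bounds.
#' @return a [ts_grid()] with out-of-range values set to `NA`.
#' @export
clip_valid_range <- function(grid, lower = -1, upper = 1) {
  stopifnot(inherits(grid, "ts_grid"))
  v <- grid$values
  v[!is.na(v) & (v < lower | v > upper)] <- NA_real_
  structure(list(values = v, times = grid$times, mask = grid$mask,
                 geometry = grid$geometry), class = "ts_grid")
}

#' Fill gaps with a centered exponentially weighted moving average
#'
#' Each missing value is replaced by the weighted mean of the available
#' observations within `window` periods on either side, with weights
#' `decay^(|dt| - 1)` (halving per step at the default `decay = 0.5`),
#' normalized over the available neighbours. Values that stay missing (no
#' neighbour within the window) leave the pixel masked.
#'
#' @param grid a [ts_grid()] possibly containing `NA` values.
#' @param window half-width of the fill window, in periods.
#' @param decay per-step weight multiplier in (0, 1].
#' @return a [ts_grid()] whose mask excludes pixels with unfillable gaps.
#' @export
fill_gaps <- function(grid, window = 3L, decay = 0.5) {
  stopifnot(inherits(grid, "ts_grid"), window >= 1L, decay > 0, decay <= 1)
  v <- grid$values
  d <- dim(v)
  Tn <- d[3]
  miss <- is.na(v)
  if (any(miss)) {
    num <- array(0, d); den <- array(0, d)
    avail <- !miss
    for (dt in c(-(window:1), 1:window)) {
      w <- decay^(abs(dt) - 1L)
      src_t <- seq_len(Tn) + dt
      ok <- src_t >= 1L & src_t <= Tn
      vv <- v[, , src_t[ok], drop = FALSE]
      av <- avail[, , src_t[ok], drop = FALSE]
      vv[!av] <- 0
      num[, , ok] <- num[, , ok] + w * vv
      den[, , ok] <- den[, , ok] + w * av
    }
    fillable <- miss & den > 0
    v[fillable] <- num[fillable] / den[fillable]
  }
  complete <- apply(is.finite(v), c(1, 2), all)
  ts_grid(v, times = grid$times, mask = grid$mask & complete,
          geometry = grid$geometry)
}

# Savitzky-Golay smoother matrix (T x T). Interior rows are the classic SG
# coefficients; rows near the series ends refit on the window truncated to the
# available range instead of padding, and the polynomial degree shrinks when
# the truncated window is too short to support it.
sg_smoother_matrix <- function(Tn, window, order) {
  stopifnot(window %% 2L == 1L, order < window)
  if (window > Tn) stop("smoothing window exceeds series length")
  h <- (window - 1L) %/% 2L
  S <- matrix(0, Tn, Tn)
  for (t in seq_len(Tn)) {
    idx <- max(1L, t - h):min(Tn, t + h)
    deg <- min(order, length(idx) - 1L)
    x <- idx - t
    A <- outer(x, 0:deg, `^`)
    # fitted value at x = 0 is the intercept of the local fit
    S[t, idx] <- solve(crossprod(A), t(A))[1L, ]
  }
  S
}

#' Savitzky-Golay smoothing of each pixel's series
#'
#' Local least-squares polynomial smoothing applied independently per pixel.
#' Near the series ends the window shrinks to the available range (no value
#' padding). With `chen_iterations > 0` an upper-envelope iteration follows
#' the approach of fitting toward the high points of a vegetation-index
#' series: points that fall below the fitted curve are replaced by the fit,
#' the series is re-smoothed, and this repeats the requested number of times.
#' The output is clamped back to `[-1, 1]`.
#'
#' @param grid a [ts_grid()] with complete series on valid pixels.
#' @param window odd window length in periods.
#' @param order polynomial degree, `< window`.
#' @param chen_iterations number of upper-envelope iterations (0 = plain
#'   smoothing).
#' @return a smoothed [ts_grid()].
#' @export
smooth_savitzky_golay <- function(grid, window = 7L, order = 2L,
                                  chen_iterations = 0L) {
  stopifnot(inherits(grid, "ts_grid"))
  pm <- flatten(grid)
  if (anyNA(pm$data))
    stop("series contain missing values; run fill_gaps first")
  S <- sg_smoother_matrix(ncol(pm$data), window, order)
  cur <- pm$data
  sm <- cur %*% t(S)
  for (i in seq_len(chen_iterations)) {
    cur <- pmax(cur, sm)
    sm <- cur %*% t(S)
  }
  sm[sm > 1] <- 1; sm[sm < -1] <- -1
  out <- unflatten(pm, sm)
  # keep the caller's mask: smoothing never invalidates pixels
  out$mask <- grid$mask & out$mask
  out
}

#' Full preprocessing chain
#'
#' Range filter, gap fill, then Savitzky-Golay smoothing; the result is
#' complete (no missing values) on all valid pixels and lies in `[-1, 1]`.
#'
#' @param grid a [ts_grid()] of raw index values.
#' @param fill_window,fill_decay see [fill_gaps()].
#' @param sg_window,sg_order,chen_iterations see [smooth_savitzky_golay()].
#' @return a preprocessed [ts_grid()].
#' @export
preprocess_stack <- function(grid, fill_window = 3L, fill_decay = 0.5,
                             sg_window = 7L, sg_order = 2L,
                             chen_iterations = 0L) {
  g <- clip_valid_range(grid)
  g <- fill_gaps(g, window = fill_window, decay = fill_decay)
  smooth_savitzky_golay(g, window = sg_window, order = sg_order,
                        chen_iterations = chen_iterations)
}
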