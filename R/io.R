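# Minimal GeoTIFF reader/writer for time-series stacks and label rasters.
#
# Scope: uncompressed baseline TIFF, one sample per pixel, one page (IFD) per
# time period; float64 samples for series stacks, int32 for label rasters.
# Georeferencing is written as ModelPixelScale + ModelTiepoint tags (for
# axis-aligned transforms) plus a JSON ImageDescription carrying the full
# 6-coefficient transform, CRS string, period timestamps and nodata sentinel.
# The reader also accepts generic single-sample uncompressed TIFFs (uint8/16,
# int16/32, float32/64) produced by other tools.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

# ---- low-level raw helpers --------------------------------------------------

rd_uint <- function(raw, off, size, endian) {
  # 1-based offset; unsigned ints up to 4 bytes, returned as double
  b <- as.integer(raw[off:(off + size - 1L)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

rd_values <- function(raw, off, type, count, endian) {
  size <- TIFF_TYPE_SIZES[[as.character(type)]]
  bytes <- raw[off:(off + size * count - 1L)]
  con <- rawConnection(bytes)
  on.exit(close(con))
  switch(as.character(type),
    `2`  = {
      s <- readBin(con, "raw", n = count)
      rawToChar(s[s != as.raw(0)])
    },
    `3`  = readBin(con, "integer", n = count, size = 2L, signed = FALSE,
                   endian = endian),
    `4`  = {
      v <- readBin(con, "integer", n = count, size = 4L, endian = endian)
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    `12` = readBin(con, "double", n = count, size = 8L, endian = endian),
    `1`  = as.integer(readBin(con, "raw", n = count)),
    stop("unsupported TIFF field type: ", type)
  )
}

parse_ifds <- function(raw, endian) {
  next_off <- rd_uint(raw, 5L, 4L, endian)
  ifds <- list()
  while (next_off != 0) {
    n <- rd_uint(raw, next_off + 1L, 2L, endian)
    entries <- list()
    for (i in seq_len(n)) {
      eoff <- next_off + 2L + (i - 1L) * 12L + 1L
      tag <- rd_uint(raw, eoff, 2L, endian)
      type <- rd_uint(raw, eoff + 2L, 2L, endian)
      count <- rd_uint(raw, eoff + 4L, 4L, endian)
      size <- TIFF_TYPE_SIZES[as.character(type)]
      if (is.na(size)) next   # skip field types we do not model
      voff <- if (size * count <= 4) eoff + 8L
              else rd_uint(raw, eoff + 8L, 4L, endian) + 1L
      entries[[as.character(tag)]] <- rd_values(raw, voff, type, count, endian)
    }
    ifds[[length(ifds) + 1L]] <- entries
    next_off <- rd_uint(raw, next_off + 2L + n * 12L + 1L, 4L, endian)
  }
  ifds
}

read_page_matrix <- function(raw, e, endian) {
  W <- as.integer(e[["256"]]); H <- as.integer(e[["257"]])
  bits <- if (is.null(e[["258"]])) 1L else as.integer(e[["258"]][1])
  comp <- if (is.null(e[["259"]])) 1L else as.integer(e[["259"]])
  if (comp != 1L) stop("only uncompressed TIFF is supported")
  spp <- if (is.null(e[["277"]])) 1L else as.integer(e[["277"]])
  if (spp != 1L) stop("only single-sample TIFF is supported")
  fmt <- if (is.null(e[["339"]])) 1L else as.integer(e[["339"]][1])
  offs <- e[["273"]]; counts <- e[["279"]]
  bytes <- raw(0)
  for (s in seq_along(offs))
    bytes <- c(bytes, raw[(offs[s] + 1L):(offs[s] + counts[s])])
  con <- rawConnection(bytes)
  on.exit(close(con))
  n <- W * H
  vals <- if (fmt == 3L) {
    readBin(con, "double", n = n, size = bits / 8L, endian = endian)
  } else if (fmt == 2L) {
    readBin(con, "integer", n = n, size = bits / 8L, signed = TRUE,
            endian = endian)
  } else {
    if (bits > 16L) stop("unsigned samples over 16 bits are not supported")
    readBin(con, "integer", n = n, size = bits / 8L, signed = FALSE,
            endian = endian)
  }
  matrix(vals, nrow = H, ncol = W, byrow = TRUE)
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (rd_uint(raw, 3L, 2L, endian) != 42)
    stop("not a TIFF file: ", path)
  ifds <- parse_ifds(raw, endian)
  if (!length(ifds)) stop("TIFF file has no images: ", path)
  pages <- lapply(ifds, read_page_matrix, raw = raw, endian = endian)
  meta <- list()
  e1 <- ifds[[1]]
  if (!is.null(e1[["270"]]))
    meta <- tryCatch(jsonlite::fromJSON(e1[["270"]]),
                     error = function(err) list(description = e1[["270"]]))
  if (is.null(meta$transform) &&
      !is.null(e1[["33550"]]) && !is.null(e1[["33922"]])) {
    sc <- e1[["33550"]]; tp <- e1[["33922"]]
    meta$transform <- c(tp[4] - tp[1] * sc[1], sc[1], 0,
                        tp[5] + tp[2] * sc[2], 0, -sc[2])
  }
  list(pages = pages, meta = meta)
}

# ---- writer -----------------------------------------------------------------

wr_entry <- function(con, tag, type, count, value, offset = NULL) {
  writeBin(as.integer(c(tag, type)), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  size <- TIFF_TYPE_SIZES[[as.character(type)]] * count
  if (!is.null(offset)) {
    writeBin(as.integer(offset), con, size = 4L, endian = "little")
  } else if (type == 3) {
    writeBin(as.integer(c(value, rep(0L, 2 - count))), con, size = 2L,
             endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
  invisible(size)
}

write_tiff_pages <- function(pages, path, sample_format = c("float", "int"),
                             meta = list()) {
  sample_format <- match.arg(sample_format)
  bits <- if (sample_format == "float") 64L else 32L
  fmt_code <- if (sample_format == "float") 3L else 2L
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  page_bytes <- H * W * bits / 8L
  desc <- charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  desc <- c(desc, as.raw(0))
  if (length(desc) %% 2L) desc <- c(desc, as.raw(0))
  gt <- meta$transform
  axis_aligned <- !is.null(gt) && gt[3] == 0 && gt[5] == 0 && gt[6] < 0
  np <- length(pages)

  off <- 8
  data_off <- off + (seq_len(np) - 1) * page_bytes
  off <- off + np * page_bytes
  desc_off <- off; off <- off + length(desc)
  scale_off <- tie_off <- NULL
  if (axis_aligned) {
    scale_off <- off; off <- off + 24
    tie_off <- off; off <- off + 48
  }
  ntags1 <- 11L + if (axis_aligned) 2L else 0L
  ntags  <- 10L
  ifd_off <- numeric(np)
  ifd_off[1] <- off
  if (np > 1)
    ifd_off[2:np] <- off + (2 + 12 * ntags1 + 4) +
      (seq_len(np - 1) - 1) * (2 + 12 * ntags + 4)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4L, endian = "little")
  for (p in seq_len(np)) {
    m <- pages[[p]]
    v <- as.numeric(t(m))           # row-major sample order
    if (sample_format == "float")
      writeBin(v, con, size = 8L, endian = "little")
    else
      writeBin(as.integer(v), con, size = 4L, endian = "little")
  }
  writeBin(desc, con)
  if (axis_aligned) {
    writeBin(c(gt[2], -gt[6], 0), con, size = 8L, endian = "little")
    writeBin(c(0, 0, 0, gt[1], gt[4], 0), con, size = 8L, endian = "little")
  }
  for (p in seq_len(np)) {
    first <- p == 1L
    nt <- if (first) ntags1 else ntags
    writeBin(as.integer(nt), con, size = 2L, endian = "little")
    wr_entry(con, 256, 4, 1, W)
    wr_entry(con, 257, 4, 1, H)
    wr_entry(con, 258, 3, 1, bits)
    wr_entry(con, 259, 3, 1, 1)
    wr_entry(con, 262, 3, 1, 1)
    if (first) wr_entry(con, 270, 2, length(desc), NULL, offset = desc_off)
    wr_entry(con, 273, 4, 1, data_off[p])
    wr_entry(con, 277, 3, 1, 1)
    wr_entry(con, 278, 4, 1, H)
    wr_entry(con, 279, 4, 1, page_bytes)
    wr_entry(con, 339, 3, 1, fmt_code)
    if (first && axis_aligned) {
      wr_entry(con, 33550, 12, 3, NULL, offset = scale_off)
      wr_entry(con, 33922, 12, 6, NULL, offset = tie_off)
    }
    nxt <- if (p < np) ifd_off[p + 1] else 0
    writeBin(as.integer(nxt), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---- public API -------------------------------------------------------------

#' Read a multi-band GeoTIFF stack
#'
#' One band per time period. Cells that are non-finite or equal to the nodata
#' sentinel become missing; pixels missing in any period are masked.
#'
#' @param path GeoTIFF file path.
#' @param dates optional character vector (or path to a one-date-per-line CSV)
#'   of ISO-8601 dates, length T; overrides dates embedded in the file.
#' @param nodata optional nodata sentinel; defaults to the embedded value
#'   (`NaN` for stacks written by [write_stack()]).
#' @return a [ts_grid()].
#' @export
read_stack <- function(path, dates = NULL, nodata = NULL) {
  tf <- read_tiff_pages(path)
  np <- length(tf$pages)
  H <- nrow(tf$pages[[1]]); W <- ncol(tf$pages[[1]])
  vals <- array(NA_real_, c(H, W, np))
  for (p in seq_len(np)) vals[, , p] <- tf$pages[[p]]
  if (is.null(nodata)) nodata <- tf$meta$nodata
  if (!is.null(nodata) && is.finite(suppressWarnings(as.numeric(nodata))))
    vals[vals == as.numeric(nodata)] <- NA_real_
  vals[!is.finite(vals)] <- NA_real_
  if (is.character(dates) && length(dates) == 1L && file.exists(dates))
    dates <- read_dates_csv(dates)
  if (is.null(dates) && !is.null(tf$meta$times)) dates <- tf$meta$times
  if (!is.null(dates) && length(dates) != np)
    stop(sprintf("band count (%d) does not match number of dates (%d)",
                 np, length(dates)))
  gt <- if (!is.null(tf$meta$transform)) as.numeric(tf$meta$transform)
        else c(0, 1, 0, 0, 0, -1)
  crs <- if (!is.null(tf$meta$crs)) tf$meta$crs else ""
  geom <- grid_geometry(H, W, gt, crs)
  ts_grid(vals, times = dates, geometry = geom)
}

#' Write a time-series stack as a multi-band GeoTIFF
#'
#' Float64 samples, one band per period; masked pixels are stored as `NaN`.
#' The geotransform, CRS, and timestamps travel in the file.
#'
#' @param grid a [ts_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "ts_grid"))
  Tn <- n_periods(grid)
  pages <- vector("list", Tn)
  for (p in seq_len(Tn)) {
    m <- grid$values[, , p]
    m[!grid$mask] <- NaN
    m[is.na(m)] <- NaN
    pages[[p]] <- m
  }
  meta <- list(transform = grid$geometry$transform, crs = grid$geometry$crs,
               nodata = "NaN")
  if (!is.null(grid$times)) meta$times <- grid$times
  write_tiff_pages(pages, path, "float", meta)
}

#' Write a label raster as a single-band int32 GeoTIFF
#'
#' Masked pixels are written as the nodata label -1; geometry travels in the
#' file.
#'
#' @param lg a [label_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_raster <- function(lg, path) {
  stopifnot(inherits(lg, "label_grid"))
  meta <- list(transform = lg$geometry$transform, crs = lg$geometry$crs,
               nodata = -1, kind = lg$kind)
  write_tiff_pages(list(lg$labels), path, "int", meta)
}

#' Read a label raster written by [write_label_raster()]
#'
#' @param path GeoTIFF file path (single band, integer samples).
#' @param kind label kind; defaults to the embedded kind or `"superpixel"`.
#' @return a [label_grid()].
#' @export
read_label_raster <- function(path, kind = NULL) {
  tf <- read_tiff_pages(path)
  m <- tf$pages[[1]]
  storage.mode(m) <- "integer"
  if (is.null(kind))
    kind <- if (!is.null(tf$meta$kind)) tf$meta$kind else "superpixel"
  gt <- if (!is.null(tf$meta$transform)) as.numeric(tf$meta$transform)
        else c(0, 1, 0, 0, 0, -1)
  crs <- if (!is.null(tf$meta$crs)) tf$meta$crs else ""
  label_grid(m, kind, grid_geometry(nrow(m), ncol(m), gt, crs))
}

#' Read a one-ISO-date-per-line CSV
#' @param path file with one date per line (no header).
#' @return character vector of dates.
#' @export
read_dates_csv <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write per-segment mean series as CSV
#'
#' Columns `segment_id, t0..t{T-1}`.
#' @param series numeric `k x T` matrix of segment mean series (rows ordered
#'   by segment id 0..k-1), e.g. the `series` field of a superpixel set.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(segment_id = seq_len(nrow(series)) - 1L, series)
  names(df) <- c("segment_id", paste0("t", seq_len(ncol(series)) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
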