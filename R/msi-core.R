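# Gridded MSI data model: per-pixel spectra, mass-channel extraction, tile
# assembly, and ROI arithmetic. Pixel coordinates are 0-based (row, col) with
# pixel centers at integer coordinates; m/z windows are closed intervals.

#' Channel image
#'
#' A single-channel 2D intensity image from one imaging modality: an extracted
#' m/z window of an MSI dataset or a named protein channel.
#'
#' @param values Numeric matrix of non-negative finite intensities.
#' @param pixel_size Pixel edge length in micrometers.
#' @param modality One of `"gcib_lipid"`, `"c60_protein"`, `"maldi"`,
#'   `"other"`.
#' @param channel Channel name (e.g. `"PE(40:4)"`, `"K14"`), or `NULL`.
#' @param window Optional numeric `c(center, half_width)` m/z window (Da).
#' @param mask Optional logical matrix of valid pixels (same shape).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(values, pixel_size = 1, modality = "other",
                          channel = NULL, window = NULL, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("channel values must be finite")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(values))) stop("mask shape must match values")
    storage.mode(mask) <- "logical"
  }
  structure(
    list(values = values, pixel_size = pixel_size, modality = modality,
         channel = channel, window = window, mask = mask),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %dx%d px (%.3g um/px), modality %s%s\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$modality,
              if (!is.null(x$channel)) paste0(", channel ", x$channel) else ""))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$values)

# Guard used by operations that mix two images: shapes must agree and, unless
# explicitly allowed, modalities must match (mixing modalities without
# registration is an error).
check_compatible <- function(a, b, allow_modality_mismatch = FALSE) {
  stopifnot(inherits(a, "channel_image"), inherits(b, "channel_image"))
  if (!all(dim(a$values) == dim(b$values))) {
    stop("channel images have different shapes: ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"))
  }
  if (!allow_modality_mismatch && !identical(a$modality, b$modality)) {
    stop("refusing to combine channels from different modalities (",
         a$modality, " vs ", b$modality, ") without registration")
  }
  invisible(TRUE)
}

#' Rectangular region of interest
#'
#' @param row0,col0 0-based top-left pixel of the region.
#' @param height,width Region extent in pixels.
#' @return An object of class `roi`.
#' @export
roi <- function(row0, col0, height, width) {
  if (height < 1 || width < 1) stop("roi extent must be positive")
  if (row0 < 0 || col0 < 0) stop("roi origin must be non-negative")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

roi_index <- function(r, image) {
  d <- dim(image$values)
  if (r$row0 + r$height > d[1] || r$col0 + r$width > d[2]) {
    stop("roi extends outside the image")
  }
  list(rows = (r$row0 + 1L):(r$row0 + r$height),
       cols = (r$col0 + 1L):(r$col0 + r$width))
}

#' Mean intensity within an ROI
#'
#' Arithmetic mean of the image values inside the region, restricted to the
#' image mask when one is present.
#'
#' @param image A [channel_image()].
#' @param r An [roi()], fully inside the image.
#' @return Mean intensity (scalar).
#' @export
roi_mean <- function(image, r) {
  idx <- roi_index(r, image)
  v <- image$values[idx$rows, idx$cols]
  if (!is.null(image$mask)) {
    m <- image$mask[idx$rows, idx$cols]
    if (!any(m)) stop("roi contains no valid (unmasked) pixels")
    v <- v[m]
  }
  mean(v)
}

#' Sample random square ROIs
#'
#' Draws `k` distinct `size` x `size` ROI positions uniformly from all
#' positions whose full footprint lies inside the image (and inside `mask`
#' when given). Sampling is without replacement of positions; overlapping
#' regions are allowed.
#'
#' @param image A [channel_image()].
#' @param k Number of regions.
#' @param size Region edge length in pixels.
#' @param seed Integer seed for reproducibility.
#' @param mask Optional logical matrix; the whole footprint must lie in it.
#' @return A list of [roi()] objects of length `k`.
#' @export
sample_rois <- function(image, k = 13, size = 15, seed = 1, mask = NULL) {
  d <- dim(image$values)
  if (d[1] < size || d[2] < size) stop("image smaller than requested roi size")
  nr <- d[1] - size + 1L
  nc <- d[2] - size + 1L
  if (is.null(mask)) {
    valid <- matrix(TRUE, nr, nc)
  } else {
    mask <- as.matrix(mask)
    stopifnot(all(dim(mask) == d))
    # integral image: footprint valid iff all size x size pixels are in mask
    cs <- apply(mask * 1, 2, cumsum)            # cumulative over rows
    cs <- t(apply(cs, 1, cumsum))               # then over columns
    ii <- rbind(0, cbind(0, cs))                # ii[i+1, j+1] = sum mask[1:i, 1:j]
    counts <- ii[(size + 1):(d[1] + 1), (size + 1):(d[2] + 1)] -
      ii[1:nr, (size + 1):(d[2] + 1)] -
      ii[(size + 1):(d[1] + 1), 1:nc] +
      ii[1:nr, 1:nc]
    valid <- counts == size * size
  }
  pos <- which(valid)
  if (length(pos) < k) {
    stop("only ", length(pos), " valid roi positions for k = ", k)
  }
  chosen <- with_seed(seed, sample(pos, k, replace = FALSE))
  lapply(chosen, function(p) {
    r0 <- (p - 1L) %% nr          # column-major index -> (row, col)
    c0 <- (p - 1L) %/% nr
    roi(r0, c0, size, size)
  })
}

# Run expr under a temporary RNG state so package functions are reproducible
# without clobbering the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Gridded MSI dataset
#'
#' Per-pixel centroided spectra on a rectangular pixel grid, stored row-major
#' as parallel lists of m/z and intensity vectors.
#'
#' @param mz List (length rows*cols, row-major) of strictly increasing m/z
#'   vectors, or a single shared numeric axis for continuous-mode data.
#' @param intensity List of non-negative intensity vectors (same lengths as
#'   the corresponding `mz` element), or a `npixels x length(axis)` matrix
#'   when `mz` is a shared axis.
#' @param shape Integer `c(rows, cols)`.
#' @param pixel_size Pixel size in micrometers.
#' @param modality Modality tag (see [channel_image()]).
#' @return An object of class `msi_grid`.
#' @export
msi_grid <- function(mz, intensity, shape, pixel_size = 1,
                     modality = "gcib_lipid") {
  shape <- as.integer(shape)
  n <- prod(shape)
  if (is.numeric(mz) && is.matrix(intensity)) {
    stopifnot(nrow(intensity) == n, ncol(intensity) == length(mz))
    mz <- rep(list(as.numeric(mz)), n)
    intensity <- lapply(seq_len(n), function(i) as.numeric(intensity[i, ]))
  }
  stopifnot(length(mz) == n, length(intensity) == n)
  for (i in seq_len(n)) {
    if (length(mz[[i]]) != length(intensity[[i]])) {
      stop("pixel ", i, ": mz and intensity lengths differ")
    }
    if (length(mz[[i]]) > 1 && any(diff(mz[[i]]) <= 0)) {
      stop("pixel ", i, ": mz values must be strictly increasing")
    }
    if (any(intensity[[i]] < 0)) stop("pixel ", i, ": negative intensity")
  }
  structure(list(mz = mz, intensity = intensity, shape = shape,
                 pixel_size = pixel_size, modality = modality),
            class = "msi_grid")
}

#' @export
print.msi_grid <- function(x, ...) {
  cat(sprintf("<msi_grid> %dx%d px (%.3g um/px), modality %s, %d peaks total\n",
              x$shape[1], x$shape[2], x$pixel_size, x$modality,
              sum(lengths(x$mz))))
  invisible(x)
}

#' Extract a mass-channel image from an MSI grid
#'
#' Sums, per pixel, all peak intensities whose m/z lies in the closed window
#' `[center - half_width, center + half_width]`.
#'
#' @param grid An [msi_grid()].
#' @param center Window center, Da.
#' @param half_width Window half width, Da (default 0.05).
#' @param channel Optional channel name for the result.
#' @return A [channel_image()] on the grid's pixel raster.
#' @export
extract_channel <- function(grid, center, half_width = 0.05, channel = NULL) {
  stopifnot(inherits(grid, "msi_grid"), half_width > 0)
  lo <- center - half_width
  hi <- center + half_width
  v <- vapply(seq_along(grid$mz), function(i) {
    mzs <- grid$mz[[i]]
    sum(grid$intensity[[i]][mzs >= lo & mzs <= hi])
  }, numeric(1))
  channel_image(matrix(v, nrow = grid$shape[1], ncol = grid$shape[2],
                       byrow = TRUE),
                pixel_size = grid$pixel_size, modality = grid$modality,
                channel = channel, window = c(center, half_width))
}

#' Assemble tiles into a mosaic image
#'
#' Places uniformly shaped tiles row-major onto a `tile_rows` x `tile_cols`
#' layout, as acquired by a tiling MSI stage.
#'
#' @param tiles List of [channel_image()] tiles, length
#'   `tile_rows * tile_cols`, in row-major order.
#' @param tile_rows,tile_cols Layout dimensions.
#' @return The assembled [channel_image()].
#' @export
assemble_tiles <- function(tiles, tile_rows, tile_cols) {
  if (length(tiles) != tile_rows * tile_cols) {
    stop("expected ", tile_rows * tile_cols, " tiles, got ", length(tiles))
  }
  dims <- vapply(tiles, function(t) dim(t$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all tiles must have the same shape")
  }
  h <- dims[1, 1]; w <- dims[2, 1]
  out <- matrix(0, tile_rows * h, tile_cols * w)
  for (tr in seq_len(tile_rows)) {
    for (tc in seq_len(tile_cols)) {
      t <- tiles[[(tr - 1L) * tile_cols + tc]]
      out[((tr - 1L) * h + 1L):(tr * h), ((tc - 1L) * w + 1L):(tc * w)] <-
        t$values
    }
  }
  channel_image(out, pixel_size = tiles[[1]]$pixel_size,
                modality = tiles[[1]]$modality, channel = tiles[[1]]$channel,
                window = tiles[[1]]$window)
}

#' Split a mosaic back into tiles
#'
#' Inverse of [assemble_tiles()]; mainly for verification.
#'
#' @param image The assembled [channel_image()].
#' @param tile_rows,tile_cols Layout dimensions (must divide the image shape).
#' @return Row-major list of tiles.
#' @export
split_tiles <- function(image, tile_rows, tile_cols) {
  d <- dim(image$values)
  if (d[1] %% tile_rows != 0 || d[2] %% tile_cols != 0) {
    stop("image shape is not divisible by the tile layout")
  }
  h <- d[1] %/% tile_rows; w <- d[2] %/% tile_cols
  out <- vector("list", tile_rows * tile_cols)
  for (tr in seq_len(tile_rows)) {
    for (tc in seq_len(tile_cols)) {
      out[[(tr - 1L) * tile_cols + tc]] <- channel_image(
        image$values[((tr - 1L) * h + 1L):(tr * h),
                     ((tc - 1L) * w + 1L):(tc * w)],
        pixel_size = image$pixel_size, modality = image$modality,
        channel = image$channel, window = image$window)
    }
  }
  out
}

#' Export a channel image
#'
#' Writes the intensity matrix as CSV (no header; one row per image row) or,
#' when the `tiff` package is available, as 32-bit float TIFF.
#'
#' @param image A [channel_image()].
#' @param path Output path; format chosen by extension (`.csv` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_channel <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(image$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF export")
    }
    tiff::writeTIFF(image$values, path, bits.per.sample = 32L,
                    sample.format = "float")
  } else {
    stop("unsupported channel export format: .", ext)
  }
  invisible(path)
}

#' Read a channel image written by [write_channel()]
#'
#' @param path `.csv` or `.tif` file.
#' @param ... Passed to [channel_image()] (pixel_size, modality, channel).
#' @return A [channel_image()].
#' @export
read_channel <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  values <- if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ","))
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF import")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported channel format: .", ext)
  }
  dimnames(values) <- NULL
  channel_image(values, ...)
}
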