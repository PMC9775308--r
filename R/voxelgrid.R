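#' 3D intensity volume with physical voxel size
#'
#' The universal image carrier: a non-negative 3D intensity array ordered
#' `(z, y, x)` together with its physical voxel dimensions in micrometres.
#' Confocal stacks of skin equivalents are strongly anisotropic (default
#' 0.7 x 0.7 um laterally, 3 um axially), so every downstream distance or
#' thickness computation consumes `voxel_size` rather than voxel counts.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`, finite and >= 0.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres, all > 0.
#' @param channel free-text channel label (e.g. `"BODIPY"`, `"collagen-IV"`).
#' @return An object of class `voxel_grid` with fields `data`, `voxel_size`
#'   and `channel`.
#' @export
voxel_grid <- function(data, voxel_size = c(3, 0.7, 0.7), channel = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array ordered (z, y, x)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (dz, dy, dx) in um")
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be >= 0")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel = as.character(channel)[1L]),
            class = "voxel_grid")
}

#' Boolean mask aligned to a voxel grid
#'
#' Output container of all segmentations; carries the voxel size of the
#' grid it was derived from.
#'
#' @param mask 3D logical array, `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return An object of class `binary_volume` with fields `mask`, `voxel_size`.
#' @export
binary_volume <- function(mask, voxel_size = c(3, 0.7, 0.7)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D logical array ordered (z, y, x)")
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask may not contain NA")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values")
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size)),
            class = "binary_volume")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %s%d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              if (nzchar(x$channel)) paste0("[", x$channel, "] ") else "",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d voxels, %d foreground (VF %.4f)\n",
              d[1], d[2], d[3], sum(x$mask), mean(x$mask)))
  invisible(x)
}

#' Read a grayscale TIFF stack into a voxel grid
#'
#' Pages of a single- or multi-page grayscale TIFF map to z-planes.
#' Integer-typed files are read losslessly (native integer values); float
#' TIFFs are read as stored.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param voxel_size `(dz, dy, dx)` in micrometres to attach.
#' @param channel channel label to attach.
#' @return A [voxel_grid] with data shape `(pages, rows, cols)`.
#' @export
read_stack <- function(path, voxel_size = c(3, 0.7, 0.7), channel = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("zero-size TIFF: ", path)
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("RGB or multi-sample TIFF pages are not supported; supply one grayscale stack per channel")
    if (any(dim(p) == 0L)) stop("zero-size image plane in ", path)
  }
  nr <- nrow(pages[[1L]]); nc <- ncol(pages[[1L]])
  arr <- array(0, dim = c(length(pages), nr, nc))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  voxel_grid(arr, voxel_size = voxel_size, channel = channel)
}

#' Write a voxel grid as a multi-page grayscale TIFF
#'
#' With `bits` 8 or 16 the data are written as native integers (lossless
#' round trip for integer-valued input in range); with `bits = 32` a float
#' TIFF is written.
#'
#' @param grid a [voxel_grid].
#' @param path output path.
#' @param bits bits per sample: 8, 16 or 32 (float).
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, bits = 16L) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- grid$data
  nz <- dim(d)[1L]
  if (bits %in% c(8L, 16L)) {
    mx <- 2^bits - 1
    if (max(d) > mx || any(d != round(d)))
      stop("data must be integer-valued in [0, ", mx, "] for ", bits, "-bit output")
    planes <- lapply(seq_len(nz), function(z) matrix(d[z, , ] / mx, dim(d)[2L], dim(d)[3L]))
    tiff::writeTIFF(planes, path, bits.per.sample = as.integer(bits))
  } else if (bits == 32L) {
    planes <- lapply(seq_len(nz), function(z) matrix(d[z, , ], dim(d)[2L], dim(d)[3L]))
    tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  } else stop("`bits` must be 8, 16 or 32")
  invisible(path)
}

#' Extract contiguous analysis sub-volumes (tiles)
#'
#' Cuts `count` non-overlapping tiles of a requested physical XY footprint,
#' laid contiguously along x and centred in the grid, retaining full z-depth.
#' This mirrors taking several adjacent confocal fields along a strip in the
#' centre of a culture.
#'
#' @param grid a [voxel_grid].
#' @param count number of tiles (>= 1).
#' @param xy_size physical tile size `(y, x)` in micrometres.
#' @return List of `count` [voxel_grid] tiles; each carries its voxel offset
#'   (1-based `(z, y, x)` of its first voxel) in attribute `"origin"`.
#' @export
extract_subvolumes <- function(grid, count, xy_size) {
  stopifnot(inherits(grid, "voxel_grid"), count >= 1, length(xy_size) == 2L)
  d <- dim(grid$data)
  vs <- grid$voxel_size
  ty <- round(xy_size[1L] / vs[2L])
  tx <- round(xy_size[2L] / vs[3L])
  if (ty < 1L || tx < 1L) stop("tile size smaller than one voxel")
  if (ty > d[2L] || count * tx > d[3L])
    stop(sprintf("requested tiling (%d x %d px, %d tiles along x) exceeds grid extent %d x %d",
                 ty, tx, count, d[2L], d[3L]))
  ty <- as.integer(ty); tx <- as.integer(tx)
  y0 <- as.integer(floor((d[2L] - ty) / 2)) + 1L
  x0 <- as.integer(floor((d[3L] - count * tx) / 2)) + 1L
  lapply(seq_len(count), function(i) {
    xs <- x0 + (as.integer(i) - 1L) * tx
    tile <- voxel_grid(grid$data[, y0:(y0 + ty - 1L), xs:(xs + tx - 1L), drop = FALSE],
                       voxel_size = vs, channel = grid$channel)
    attr(tile, "origin") <- c(z = 1L, y = y0, x = xs)
    tile
  })
}
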