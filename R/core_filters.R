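#' Pre-processing and segmentation parameters
#'
#' Bundles the plane-wise filter settings shared by the epidermal and lipid
#' pipelines. All values are implementation defaults, not measured constants,
#' and should be tuned to the imaging conditions at hand.
#'
#' @param median_radius_px median filter radius in pixels (window
#'   `(2r+1)^2`); 0 disables.
#' @param rolling_ball_radius_px rolling-ball background radius in pixels;
#'   `NULL` disables background subtraction (e.g. for background-free
#'   synthetic volumes).
#' @param hysteresis_low,hysteresis_high hysteresis thresholds as fractions
#'   of the volume maximum, `0 <= low < high <= 1`.
#' @param disk_radius_px disk radius for plane-wise morphological
#'   closing/opening cleanup; 0 disables.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(median_radius_px = 1L,
                          rolling_ball_radius_px = 50L,
                          hysteresis_low = 0.1,
                          hysteresis_high = 0.4,
                          disk_radius_px = 6L) {
  if (median_radius_px < 0) stop("median_radius_px must be >= 0")
  if (!is.null(rolling_ball_radius_px) && rolling_ball_radius_px <= 0)
    stop("rolling_ball_radius_px must be > 0 (or NULL to disable)")
  if (hysteresis_low < 0 || hysteresis_low >= 1) stop("hysteresis_low must be in [0, 1)")
  if (hysteresis_high <= hysteresis_low || hysteresis_high > 1)
    stop("hysteresis_high must be in (hysteresis_low, 1]")
  if (disk_radius_px < 0) stop("disk_radius_px must be >= 0")
  structure(list(median_radius_px = as.integer(median_radius_px),
                 rolling_ball_radius_px = if (is.null(rolling_ball_radius_px)) NULL
                                          else as.integer(rolling_ball_radius_px),
                 hysteresis_low = hysteresis_low,
                 hysteresis_high = hysteresis_high,
                 disk_radius_px = as.integer(disk_radius_px)),
            class = "filter_params")
}

#' Plane-wise median filter
#'
#' Each z-plane is filtered independently with a `(2r+1)^2` square window
#' and mirrored (reflected) edges; there is no mixing across planes, so the
#' strong axial anisotropy of confocal stacks cannot smear layers in z.
#'
#' @param grid a [voxel_grid].
#' @param radius_px window radius in pixels; 0 returns the input.
#' @return A filtered [voxel_grid].
#' @export
median_filter_xy <- function(grid, radius_px) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius_px < 0) stop("radius must be >= 0")
  if (radius_px == 0) return(grid)
  d <- dim(grid$data)
  out <- .median_filter_xy_cpp(as.numeric(grid$data), as.integer(d), as.integer(radius_px))
  voxel_grid(array(out, d), grid$voxel_size, grid$channel)
}

#' Linear intensity rescaling by percentiles
#'
#' Maps the `low_pct` percentile to 0 and the `high_pct` percentile to 1
#' affinely, then clips to `[0, 1]`. With the defaults (0, 100) this is a
#' min-max normalisation.
#'
#' @param grid a [voxel_grid].
#' @param low_pct,high_pct percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return A rescaled [voxel_grid] with intensities in `[0, 1]`. A constant
#'   (degenerate) volume returns all zeros with a warning.
#' @export
rescale_linear <- function(grid, low_pct = 0, high_pct = 100) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stop("need 0 <= low_pct < high_pct <= 100")
  q <- quantile(grid$data, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (q[2L] <= q[1L]) {
    warning("degenerate volume (all intensities equal): returning all zeros")
    return(voxel_grid(array(0, dim(grid$data)), grid$voxel_size, grid$channel))
  }
  out <- pmin(pmax((grid$data - q[1L]) / (q[2L] - q[1L]), 0), 1)
  voxel_grid(array(out, dim(grid$data)), grid$voxel_size, grid$channel)
}

#' Plane-wise rolling-ball background subtraction
#'
#' Estimates the background of each XY plane as a grayscale opening with a
#' ball (hemisphere) structuring function of the given radius -- the surface
#' a ball of that radius traces when rolled under the intensity landscape --
#' and subtracts it. Structures narrower than the ball survive; broad
#' autofluorescent haze is removed. For radii above 16 px the plane is
#' block-downscaled (block minimum), the ball rolled at reduced radius and
#' the background bilinearly upsampled, the standard large-radius strategy.
#'
#' @param grid a [voxel_grid].
#' @param radius_px ball radius in pixels (> 0).
#' @return A background-subtracted [voxel_grid]; output is pointwise >= 0
#'   and <= input.
#' @export
rolling_ball_xy <- function(grid, radius_px) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius_px <= 0) stop("radius must be > 0")
  d <- dim(grid$data)
  if (radius_px > min(d[2L], d[3L])) stop("ball radius exceeds plane extent")
  if (radius_px <= 16L) {
    bg <- array(.rolling_ball_bg_cpp(as.numeric(grid$data), as.integer(d),
                                     as.integer(radius_px)), d)
  } else {
    s <- ceiling(radius_px / 16)
    rs <- max(2L, as.integer(round(radius_px / s)))
    bg <- array(0, d)
    for (z in seq_len(d[1L])) {
      plane <- grid$data[z, , ]
      small <- .block_min(plane, s)
      bgs <- array(.rolling_ball_bg_cpp(as.numeric(array(small, c(1L, dim(small)))),
                                        c(1L, dim(small)), rs), dim(small))
      bg[z, , ] <- .bilinear_enlarge(bgs, d[2L], d[3L], s)
    }
  }
  out <- pmax(grid$data - pmax(bg, 0), 0)
  voxel_grid(array(out, d), grid$voxel_size, grid$channel)
}

# block minimum with edge-replicated padding to a multiple of s
.block_min <- function(m, s) {
  ny <- nrow(m); nx <- ncol(m)
  nyp <- ceiling(ny / s) * s; nxp <- ceiling(nx / s) * s
  if (nyp > ny) m <- rbind(m, m[rep(ny, nyp - ny), , drop = FALSE])
  if (nxp > nx) m <- cbind(m, m[, rep(nx, nxp - nx), drop = FALSE])
  a <- array(m, c(s, nyp / s, s, nxp / s))
  apply(a, c(2L, 4L), min)
}

# bilinear upsampling of per-block values back to the full plane;
# block i maps to full-resolution centre (i - 0.5) * s + 0.5
.bilinear_enlarge <- function(small, ny, nx, s) {
  cy <- (seq_len(nrow(small)) - 0.5) * s + 0.5
  cx <- (seq_len(ncol(small)) - 0.5) * s + 0.5
  t1 <- apply(small, 2L, function(col) {
    if (length(col) == 1L) rep(col, ny)
    else stats::approx(cy, col, xout = seq_len(ny), rule = 2)$y
  })
  t1 <- matrix(t1, nrow = ny)
  t2 <- t(apply(t1, 1L, function(row) {
    if (length(row) == 1L) rep(row, nx)
    else stats::approx(cx, row, xout = seq_len(nx), rule = 2)$y
  }))
  matrix(t2, nrow = ny)
}

#' Hysteresis thresholding
#'
#' Keeps every voxel at or above the low threshold that is 26-connected (in
#' 3D) to some voxel at or above the high threshold. Thresholds are given as
#' fractions of the volume maximum, so segmentation is invariant to global
#' intensity scaling.
#'
#' @param grid a [voxel_grid].
#' @param low,high threshold fractions of the volume maximum, `low < high`.
#' @return A [binary_volume].
#' @export
hysteresis_threshold <- function(grid, low, high) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (low >= high) stop("`low` must be < `high`")
  mx <- max(grid$data)
  d <- dim(grid$data)
  if (mx <= 0) return(binary_volume(array(FALSE, d), grid$voxel_size))
  m <- .hysteresis_cpp(as.numeric(grid$data), as.integer(d), low * mx, high * mx)
  binary_volume(array(m, d), grid$voxel_size)
}

#' Plane-wise morphological closing then opening
#'
#' Applied with a 2D disk of the given radius on each z-plane: closing fills
#' gaps and holes smaller than the element, opening then removes specks
#' smaller than it. Radius 0 is the identity.
#'
#' @param mask a [binary_volume].
#' @param disk_radius_px disk radius in pixels (>= 0).
#' @return A cleaned [binary_volume].
#' @export
morph_close_open <- function(mask, disk_radius_px) {
  stopifnot(inherits(mask, "binary_volume"))
  if (disk_radius_px < 0) stop("radius must be >= 0")
  if (disk_radius_px == 0) return(mask)
  d <- dim(mask$mask)
  m <- .binary_disk_morph_cpp(as.logical(mask$mask), as.integer(d),
                              as.integer(disk_radius_px), "co")
  binary_volume(array(m, d), mask$voxel_size)
}

#' Foreground volume fraction of a mask
#'
#' @param mask a [binary_volume].
#' @return `count(TRUE) / count(total)`, dimensionless in `[0, 1]`.
#' @export
volume_fraction <- function(mask) {
  stopifnot(inherits(mask, "binary_volume"))
  if (length(mask$mask) == 0L) stop("zero-size volume")
  mean(mask$mask)
}
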