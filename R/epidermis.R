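#' Segment the epidermal layer from three marker channels
#'
#' The epidermis is localized jointly by a nuclear stain and the suprabasal
#' markers cytokeratin 10 and involucrin. Each channel is median filtered,
#' linearly rescaled and rolling-ball background corrected, the three are
#' fused by voxelwise maximum (each marker covers a different stratum, so
#' their union localizes the full layer), and the fused volume is hysteresis
#' thresholded and cleaned by plane-wise disk closing/opening.
#'
#' @param nuclei,k10,involucrin [voxel_grid]s sharing shape and voxel size.
#' @param params a [filter_params] object.
#' @return A [binary_volume] covering the epidermal layer.
#' @export
segment_epidermis <- function(nuclei, k10, involucrin, params = filter_params()) {
  chans <- list(nuclei, k10, involucrin)
  for (ch in chans) stopifnot(inherits(ch, "voxel_grid"))
  d <- dim(nuclei$data)
  if (!identical(d, dim(k10$data)) || !identical(d, dim(involucrin$data)))
    stop("the three channels must share the same shape")
  prep <- lapply(chans, .preprocess_channel, params = params)
  fused <- voxel_grid(pmax(prep[[1L]]$data, prep[[2L]]$data, prep[[3L]]$data),
                      nuclei$voxel_size, "fused")
  m <- hysteresis_threshold(fused, params$hysteresis_low, params$hysteresis_high)
  morph_close_open(m, params$disk_radius_px)
}

.preprocess_channel <- function(grid, params) {
  g <- median_filter_xy(grid, params$median_radius_px)
  g <- if (max(g$data) > min(g$data)) rescale_linear(g) else g
  if (!is.null(params$rolling_ball_radius_px))
    g <- rolling_ball_xy(g, params$rolling_ball_radius_px)
  g
}

#' Per-column layer thickness map
#'
#' For every (y, x) column the layer thickness is taken as the span between
#' the outermost occupied z-planes, counted in voxels and scaled by the
#' z-step: `(z_top - z_bottom + 1) * dz`. The voxel-count convention means a
#' one-plane layer reads `dz`, not zero. Columns with no foreground are
#' flagged invalid and excluded from all summaries.
#'
#' @param mask a [binary_volume] (layer segmentation).
#' @return An object of class `thickness_map` with fields `thickness_um`
#'   (2D `(y, x)` matrix), `valid` (2D logical) and `dz_um`.
#' @export
thickness_map <- function(mask) {
  stopifnot(inherits(mask, "binary_volume"))
  d <- dim(mask$mask)
  nz <- d[1L]
  dz <- mask$voxel_size[1L]
  zlo <- matrix(NA_integer_, d[2L], d[3L])
  zhi <- matrix(NA_integer_, d[2L], d[3L])
  for (z in seq_len(nz)) {
    pl <- matrix(mask$mask[z, , ], d[2L], d[3L])
    new_lo <- pl & is.na(zlo)
    zlo[new_lo] <- z
    zhi[pl] <- z
  }
  valid <- !is.na(zlo)
  th <- matrix(0, d[2L], d[3L])
  th[valid] <- (zhi[valid] - zlo[valid] + 1L) * dz
  structure(list(thickness_um = th, valid = valid, dz_um = dz,
                 z_bottom = zlo, z_top = zhi),
            class = "thickness_map")
}

#' Pool thickness maps into summary statistics
#'
#' Valid-column thicknesses are pooled across sub-volumes and summarized as
#' mean and median (the default). Per-tile means are also returned so the
#' alternative average-of-tile-averages order is available.
#'
#' @param maps a `thickness_map` or list of them.
#' @return An object of class `epidermis_result`: `median_thickness_um`,
#'   `mean_thickness_um`, `n_subvolumes`, `valid_fraction` and a
#'   `per_tile_mean_um` vector.
#' @export
summarize_thickness <- function(maps) {
  if (inherits(maps, "thickness_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  pooled <- unlist(lapply(maps, function(m) m$thickness_um[m$valid]))
  if (length(pooled) == 0L) stop("all columns invalid: no layer detected")
  per_tile <- vapply(maps, function(m)
    if (any(m$valid)) mean(m$thickness_um[m$valid]) else NA_real_, numeric(1))
  structure(list(median_thickness_um = median(pooled),
                 mean_thickness_um = mean(pooled),
                 n_subvolumes = length(maps),
                 valid_fraction = mean(vapply(maps, function(m) mean(m$valid), numeric(1))),
                 per_tile_mean_um = per_tile),
            class = "epidermis_result")
}

#' @export
print.epidermis_result <- function(x, ...) {
  cat(sprintf("<epidermis_result> median %.2f um, mean %.2f um over %d sub-volume(s) (valid %.1f%%)\n",
              x$median_thickness_um, x$mean_thickness_um, x$n_subvolumes,
              100 * x$valid_fraction))
  invisible(x)
}

#' Mean marker intensity over maximum projections
#'
#' Each grid is max-projected along z; projections are pooled and the mean
#' pixel intensity returned. Computed on the unsegmented field, without
#' background subtraction, as a whole-field expression readout.
#'
#' @param grids a [voxel_grid] or list of them (positions of one sample).
#' @return Mean projected intensity (arbitrary units).
#' @export
marker_intensity <- function(grids) {
  if (inherits(grids, "voxel_grid")) grids <- list(grids)
  if (length(grids) == 0L) stop("empty grid list")
  proj <- lapply(grids, function(g) apply(g$data, c(2L, 3L), max))
  mean(unlist(proj))
}
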