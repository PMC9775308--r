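#' Multiscale Hessian (Frangi) vesselness
#'
#' For each physical scale the volume is Gaussian-smoothed with per-axis
#' sigma `scale / voxel_dim` (anisotropy-aware), the Hessian is evaluated in
#' physical units with gamma = 2 scale normalisation, and the classic
#' tubularity response is computed from its eigenvalues (plate term
#' `R_A = |l2|/|l3|`, blob term `R_B = |l1|/sqrt(|l2 l3|)`, structure term
#' `S`); the voxelwise maximum over scales is returned.
#'
#' @param col4 a [voxel_grid] (vessel basement-membrane channel).
#' @param scales_um positive physical scales in micrometres.
#' @param alpha,beta Frangi sensitivity parameters for the plate and blob
#'   terms (default 0.5 each).
#' @param c structure-term sensitivity; `NULL` (default) uses half the
#'   maximum Hessian norm per scale.
#' @return A [voxel_grid] with vesselness response in `[0, 1]`.
#' @export
vesselness <- function(col4, scales_um, alpha = 0.5, beta = 0.5, c = NULL) {
  stopifnot(inherits(col4, "voxel_grid"))
  if (length(scales_um) == 0L) stop("empty scale list")
  if (any(scales_um <= 0)) stop("scales must be > 0 (um)")
  d <- dim(col4$data)
  v <- .frangi_cpp(as.numeric(col4$data), as.integer(d), col4$voxel_size,
                   as.numeric(scales_um), alpha, beta,
                   if (is.null(c)) -1.0 else c)
  voxel_grid(array(v, d), col4$voxel_size, "vesselness")
}

#' Segment vessels from a vesselness response
#'
#' Hysteresis thresholding (fractions of the response maximum) followed by
#' removal of 26-connected components smaller than `min_size_vox`.
#'
#' @param v a vesselness [voxel_grid] (from [vesselness]).
#' @param low,high hysteresis fractions of the maximum, `low < high`.
#' @param min_size_vox minimum component size in voxels; smaller components
#'   are discarded as speckle.
#' @return A [binary_volume] vessel mask.
#' @export
segment_vessels <- function(v, low = 0.3, high = 0.6, min_size_vox = 20L) {
  stopifnot(inherits(v, "voxel_grid"))
  if (low >= high) stop("`low` must be < `high`")
  m <- hysteresis_threshold(v, low, high)
  if (min_size_vox > 1L && any(m$mask)) {
    d <- dim(m$mask)
    lab <- .label_components_cpp(as.logical(m$mask), as.integer(d), 26L)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_size_vox)
    m <- binary_volume(array(lab %in% keep & lab > 0L, d), m$voxel_size)
  }
  m
}

#' Curve skeleton of a vessel mask
#'
#' Distance-ordered homotopic thinning: voxels are visited in order of
#' increasing distance-to-background and removed when they are (26,6)
#' simple points (removal preserves foreground 26-topology and background
#' 6-topology) and not curve endpoints. The surviving set is a 1-voxel-wide
#' centreline lying inside the mask that preserves the connectivity of each
#' component; on an axis-aligned digital cylinder it tracks the true axis
#' to within a voxel.
#'
#' Thinning can leave radius-scale spurs where a boundary voxel becomes a
#' curve endpoint before the cross-section has collapsed; endpoint branches
#' shorter than the largest local radius are pruned afterwards.
#'
#' @param mask a non-empty [binary_volume].
#' @param prune `TRUE` (default) removes endpoint branches shorter than the
#'   maximum skeleton-point radius (in voxels).
#' @return Integer matrix of skeleton voxel indices, one row per point,
#'   columns `z`, `y`, `x` (1-based).
#' @export
skeletonize <- function(mask, prune = TRUE) {
  stopifnot(inherits(mask, "binary_volume"))
  if (!any(mask$mask)) stop("empty mask: nothing to skeletonize")
  d <- dim(mask$mask)
  dist <- .edt_cpp(as.logical(!mask$mask), as.integer(d), mask$voxel_size)
  skel <- .thin_skeleton_cpp(as.logical(mask$mask), as.integer(d), dist)
  pts <- which(array(skel, d), arr.ind = TRUE)
  colnames(pts) <- c("z", "y", "x")
  if (prune && nrow(pts) > 2L) {
    edt <- array(dist, d)
    rad_vox <- max(edt[pts]) / min(mask$voxel_size)
    pts <- .prune_spurs(pts, max_len = ceiling(rad_vox) + 2L)
    pts <- .recenter_tails(pts, mask$mask, edt, max_len = ceiling(rad_vox) + 2L)
  }
  pts
}

# Endpoint tails can slide off the distance-transform ridge where a flat
# structure end collapses. For each endpoint: walk inward (up to max_len),
# trim the tail back to its maximal-EDT voxel, then regrow along the ridge
# (steps of non-increasing EDT with direction continuity).
.recenter_tails <- function(pts, mask, edt, max_len) {
  key <- function(p) paste(p[1L], p[2L], p[3L])
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(pts))) assign(key(pts[i, ]), i, envir = lookup)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nb_idx <- function(p) {
    out <- integer(0)
    for (r in seq_len(nrow(offs))) {
      j <- lookup[[key(p + offs[r, ])]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(seq_len(nrow(pts)), function(i) length(nb_idx(pts[i, ])), integer(1))
  drop <- logical(nrow(pts))
  grown <- NULL
  d <- dim(mask)
  in_vol <- function(p) all(p >= 1L) && p[1L] <= d[1L] && p[2L] <= d[2L] && p[3L] <= d[3L]
  for (e in which(deg == 1L)) {
    path <- e
    prev <- -1L; cur <- e
    while (length(path) <= max_len) {
      nxt <- setdiff(nb_idx(pts[cur, ]), prev)
      if (length(nxt) != 1L || deg[nxt] >= 3L) break
      prev <- cur; cur <- nxt
      path <- c(path, cur)
    }
    vals <- edt[pts[path, , drop = FALSE]]
    istar <- min(which(vals == max(vals)))      # outermost maximal-EDT voxel
    if (istar == 1L) next                       # tail already on the ridge
    drop[path[seq_len(istar - 1L)]] <- TRUE
    tip <- pts[path[istar], ]
    prev_dir <- if (istar < length(path)) tip - pts[path[istar + 1L], ] else c(0L, 0L, 0L)
    visited <- new.env(hash = TRUE, parent = emptyenv())
    for (s in seq_len(max_len)) {
      best <- NULL; best_edt <- -Inf; best_dot <- -Inf
      for (r in seq_len(nrow(offs))) {
        q <- tip + offs[r, ]
        if (!in_vol(q) || !mask[q[1L], q[2L], q[3L]]) next
        k <- key(q)
        j <- lookup[[k]]
        if ((!is.null(j) && !drop[j]) || !is.null(visited[[k]])) next
        ed <- edt[q[1L], q[2L], q[3L]]
        if (ed > edt[tip[1L], tip[2L], tip[3L]] + 1e-9) next
        dt <- sum(offs[r, ] * prev_dir) /
          sqrt(sum(offs[r, ]^2) * max(sum(prev_dir^2), 1L))
        if (any(prev_dir != 0L) && dt <= 0) next
        if (ed > best_edt + 1e-12 || (abs(ed - best_edt) <= 1e-12 && dt > best_dot)) {
          best <- q; best_edt <- ed; best_dot <- dt
        }
      }
      if (is.null(best)) break
      assign(key(best), TRUE, envir = visited)
      grown <- rbind(grown, best)
      prev_dir <- best - tip
      tip <- best
    }
  }
  out <- pts[!drop, , drop = FALSE]
  if (!is.null(grown)) {
    grown <- matrix(as.integer(grown), ncol = 3L,
                    dimnames = list(NULL, c("z", "y", "x")))
    out <- unique(rbind(out, grown))
  }
  out
}

# Remove endpoint branches of <= max_len voxels that terminate at a junction
# (>= 3 neighbours). Branches that span endpoint-to-endpoint (isolated
# simple paths) are kept, so small components survive intact.
.prune_spurs <- function(pts, max_len) {
  repeat {
    key <- paste(pts[, 1L], pts[, 2L], pts[, 3L])
    idx <- seq_len(nrow(pts))
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (i in idx) assign(key[i], i, envir = lookup)
    nb <- function(i) {
      out <- integer(0)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        k <- paste(pts[i, 1L] + dz, pts[i, 2L] + dy, pts[i, 3L] + dx)
        j <- lookup[[k]]
        if (!is.null(j)) out <- c(out, j)
      }
      out
    }
    deg <- vapply(idx, function(i) length(nb(i)), integer(1))
    drop <- logical(nrow(pts))
    for (e in idx[deg == 1L]) {
      path <- e
      prev <- -1L
      cur <- e
      repeat {
        nxt <- setdiff(nb(cur), prev)
        if (length(nxt) != 1L) { path <- NULL; break }   # endpoint or junction reached
        if (deg[nxt] >= 3L) break                         # spur terminating at junction
        prev <- cur; cur <- nxt
        path <- c(path, cur)
        if (length(path) > max_len) { path <- NULL; break }
      }
      if (!is.null(path) && length(path) <= max_len) drop[path] <- TRUE
    }
    if (!any(drop)) return(pts)
    pts <- pts[!drop, , drop = FALSE]
    if (nrow(pts) <= 2L) return(pts)
  }
}

#' Vessel diameters along the skeleton
#'
#' The Euclidean distance transform of the vessel mask (physical-unit
#' distance of each vessel voxel to the nearest background voxel centre,
#' respecting anisotropic voxel dimensions) is sampled at the skeleton
#' points; the local diameter is twice that radius. The centre-to-centre
#' convention means an isolated single voxel reads one voxel-unit radius
#' (a documented small-structure bias).
#'
#' @param mask a [binary_volume].
#' @param skeleton skeleton point matrix from [skeletonize] (rows `(z,y,x)`).
#' @param voxel_size `(dz, dy, dx)` in micrometres; defaults to the mask's.
#' @return List with `diameters_um` (per skeleton point) and `median_um`.
#' @export
diameters_along_skeleton <- function(mask, skeleton, voxel_size = NULL) {
  stopifnot(inherits(mask, "binary_volume"))
  if (is.null(voxel_size)) voxel_size <- mask$voxel_size
  d <- dim(mask$mask)
  idx <- cbind(skeleton[, 1L], skeleton[, 2L], skeleton[, 3L])
  if (!all(mask$mask[idx])) stop("skeleton point outside mask")
  dist <- .edt_cpp(as.logical(!mask$mask), as.integer(d), as.numeric(voxel_size))
  dist <- array(dist, d)
  diam <- 2 * dist[idx]
  list(diameters_um = diam, median_um = median(diam))
}

#' Diffusion length: coverage quantile of tissue-to-vessel distance
#'
#' Every non-vessel (tissue) voxel is assigned its physical-unit Euclidean
#' distance to the nearest vessel voxel; the diffusion length is the
#' `coverage` quantile (default 0.90, linear interpolation between order
#' statistics) of those distances -- the radius around the network within
#' which 90 percent of the tissue volume lies. Lower values mean denser
#' vascularization. Vessel voxels themselves (distance 0) are excluded from
#' the quantile.
#'
#' @param mask a non-empty [binary_volume] vessel mask.
#' @param voxel_size `(dz, dy, dx)` in micrometres; defaults to the mask's.
#' @param coverage tissue-volume fraction to encompass, in (0, 1).
#' @return Diffusion length in micrometres (0 for an all-vessel mask).
#' @export
diffusion_length <- function(mask, voxel_size = NULL, coverage = 0.90) {
  stopifnot(inherits(mask, "binary_volume"))
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  if (!any(mask$mask)) stop("empty vessel mask: distances undefined")
  if (all(mask$mask)) return(0)
  if (is.null(voxel_size)) voxel_size <- mask$voxel_size
  d <- dim(mask$mask)
  dist <- .edt_cpp(as.logical(mask$mask), as.integer(d), as.numeric(voxel_size))
  unname(quantile(dist[!mask$mask], coverage, names = FALSE, type = 7))
}

#' Bundle a vessel mask with its skeleton and radii
#'
#' Convenience constructor running [skeletonize] and
#' [diameters_along_skeleton] on a segmented mask.
#'
#' @param mask a non-empty [binary_volume] vessel mask.
#' @return An object of class `vessel_network`: `mask`, `skeleton_points`,
#'   `radii_um`, `voxel_size`.
#' @export
vessel_network <- function(mask) {
  stopifnot(inherits(mask, "binary_volume"))
  pts <- skeletonize(mask)
  di <- diameters_along_skeleton(mask, pts)
  structure(list(mask = mask, skeleton_points = pts,
                 radii_um = di$diameters_um / 2,
                 voxel_size = mask$voxel_size),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d skeleton points, VF %.4f, median diameter %.2f um\n",
              nrow(x$skeleton_points), mean(x$mask$mask),
              median(2 * x$radii_um)))
  invisible(x)
}

#' Per-sample vascular metrics
#'
#' Aggregates one or more sub-volume networks into the three vascular
#' readouts: median skeleton diameter, vascular volume fraction and
#' diffusion length, each averaged across sub-volumes (the per-sample value
#' is the mean over fields of view).
#'
#' @param networks a `vessel_network` or list of them (one per sub-volume).
#' @param coverage coverage fraction for the diffusion length.
#' @return An object of class `vascular_result`: `median_diameter_um`,
#'   `vascular_vf`, `rk_um`, `coverage`, `n_subvolumes`.
#' @export
vascular_metrics <- function(networks, coverage = 0.90) {
  if (inherits(networks, "vessel_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1L)
  md <- vapply(networks, function(n) median(2 * n$radii_um), numeric(1))
  vf <- vapply(networks, function(n) volume_fraction(n$mask), numeric(1))
  rk <- vapply(networks, function(n)
    diffusion_length(n$mask, coverage = coverage), numeric(1))
  structure(list(median_diameter_um = mean(md), vascular_vf = mean(vf),
                 rk_um = mean(rk), coverage = coverage,
                 n_subvolumes = length(networks)),
            class = "vascular_result")
}

#' @export
print.vascular_result <- function(x, ...) {
  cat(sprintf("<vascular_result> median diameter %.2f um, VF %.4f, R_k %.1f um (coverage %.0f%%, n = %d)\n",
              x$median_diameter_um, x$vascular_vf, x$rk_um,
              100 * x$coverage, x$n_subvolumes))
  invisible(x)
}
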