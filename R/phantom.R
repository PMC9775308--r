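# Synthetic multi-channel confocal phantoms with exact geometric ground
# truth. Every generator is a pure function of (spec, seed): identical specs
# give bit-identical volumes. Geometry is rasterized in physical micrometre
# space with voxel-centre sampling (centre of voxel i at (i - 0.5) * d), so
# anisotropy errors are visible to the tests that consume the truth.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.axis_coords <- function(n, d) (seq_len(n) - 0.5) * d

#' Phantom scene description
#'
#' Collects the generative parameters of the synthetic skin-equivalent
#' scene. Only the blocks needed by a given generator must be present.
#' Defaults emulate the study conditions: anisotropic 3 x 0.7 x 0.7 um
#' voxels, an epidermal slab of ~90 um mean thickness, ~5 um radius vessel
#' tubes, and lipid droplets confined to a basal (hypodermal) layer.
#'
#' @param shape_vox volume shape `(nz, ny, nx)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param epidermis list: `mean_thickness_um`, `sd_um`,
#'   `surface_roughness_um` (lateral correlation of the thickness field),
#'   `intensity`, `texture_amplitude` (relative cellular texture depth in
#'   `[0, 1)`), `texture_scale_um` (texture correlation length), `z_top`
#'   (first slab plane, voxels).
#' @param vessels list of tubes, each `list(control_points = k x 3 matrix of
#'   (z, y, x) um coordinates, radius_um, intensity)`.
#' @param droplets list: `n`, `radius_range_um`, `intensity`,
#'   `layer_z_range_um` (physical z-interval holding the droplet layer).
#' @param noise list: `gaussian_sd`, `background_ramp_amplitude`,
#'   `autofluor_blob_density` (blobs per 10^6 voxels), `blob_intensity`,
#'   `blob_sigma_um`.
#' @param seed integer seed; every generator consuming the spec is a pure
#'   function of (spec, seed).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_vox = c(40L, 128L, 128L),
                         voxel_size = c(3, 0.7, 0.7),
                         epidermis = list(),
                         vessels = list(),
                         droplets = list(),
                         noise = list(),
                         seed = 1L) {
  stopifnot(length(shape_vox) == 3L, all(shape_vox >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  epi_def <- list(mean_thickness_um = 90, sd_um = 5, surface_roughness_um = 10,
                  intensity = 1, texture_amplitude = 0.5, texture_scale_um = 3,
                  z_top = 2L)
  drop_def <- list(n = 30L, radius_range_um = c(6, 12), intensity = 1,
                   layer_z_range_um = NULL)
  noise_def <- list(gaussian_sd = 0, background_ramp_amplitude = 0,
                    autofluor_blob_density = 0, blob_intensity = 0.5,
                    blob_sigma_um = 5)
  structure(list(shape_vox = as.integer(shape_vox),
                 voxel_size = as.numeric(voxel_size),
                 epidermis = utils::modifyList(epi_def, epidermis),
                 vessels = vessels,
                 droplets = utils::modifyList(drop_def, droplets),
                 noise = utils::modifyList(noise_def, noise),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smoothed, unit-variance Gaussian random field on a (ny, nx) lattice
.smooth_field <- function(ny, nx, sigma_px) {
  f <- matrix(rnorm(ny * nx), ny, nx)
  if (sigma_px > 0.05) {
    v <- .gauss_smooth_cpp(as.numeric(array(f, c(1L, ny, nx))),
                           c(1L, ny, nx), c(0, sigma_px, sigma_px))
    f <- matrix(v, ny, nx)
  }
  s <- sd(f)
  if (s > 0) f <- (f - mean(f)) / s
  f
}

#' Epidermal slab phantom with exact per-column extents
#'
#' Generates a z-contiguous bright slab whose per-column thickness is a
#' smoothed Gaussian field (given mean and SD, lateral correlation set by
#' the surface roughness), with multiplicative cellular texture (confocal
#' planes through an epidermis are never flat) shared across markers.
#' The cytokeratin-10 channel spans the whole slab, involucrin its upper
#' half (a stratum-corneum marker), and the nuclei channel adds punctate
#' spots within the slab over a dim cytoplasmic base.
#'
#' @param spec a [phantom_spec]; uses blocks `shape_vox`, `voxel_size`,
#'   `epidermis`, `seed`.
#' @return List with [voxel_grid]s `nuclei`, `k10`, `involucrin` and
#'   `truth`: `z_bottom`/`z_top` (per-column 1-based plane indices),
#'   `thickness_um` (per-column), `mask` (the exact rasterized slab as a
#'   [binary_volume]).
#' @export
make_epidermis_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_vox; vs <- spec$voxel_size; e <- spec$epidermis
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]; dz <- vs[1L]
  .with_seed(spec$seed, {
    th <- matrix(e$mean_thickness_um, ny, nx)
    if (e$sd_um > 0)
      th <- th + e$sd_um * .smooth_field(ny, nx, e$surface_roughness_um / vs[2L])
    nvox <- pmax(1L, pmin(as.integer(round(th / dz)), nz - e$z_top + 1L))
    if (e$mean_thickness_um / dz > nz - e$z_top + 1L)
      stop("slab thicker than volume")
    z_lo <- matrix(e$z_top, ny, nx)
    z_hi <- z_lo + matrix(nvox, ny, nx) - 1L
    zidx <- array(rep(seq_len(nz), ny * nx), c(nz, ny, nx))
    lo3 <- aperm(array(z_lo, c(ny, nx, nz)), c(3L, 1L, 2L))
    hi3 <- aperm(array(z_hi, c(ny, nx, nz)), c(3L, 1L, 2L))
    slab <- zidx >= lo3 & zidx <= hi3
    # shared multiplicative texture, correlation texture_scale_um
    tex <- array(runif(nz * ny * nx), c(nz, ny, nx))
    tex <- array(.gauss_smooth_cpp(as.numeric(tex), d,
                                   c(0.5, e$texture_scale_um / vs[2L],
                                     e$texture_scale_um / vs[3L])), d)
    rng <- range(tex)
    tex <- if (diff(rng) > 0) (tex - rng[1L]) / diff(rng) else tex * 0 + 1
    tex <- (1 - e$texture_amplitude) + e$texture_amplitude * tex
    mid3 <- (lo3 + hi3) / 2
    k10 <- e$intensity * tex * slab
    inv <- e$intensity * tex * (slab & zidx <= mid3 + 0.5)
    # punctate nuclei over a dim base
    nuc <- 0.3 * e$intensity * tex * slab
    n_spots <- max(1L, as.integer(ny * nx / 64))
    sy <- sample.int(ny, n_spots, replace = TRUE)
    sx <- sample.int(nx, n_spots, replace = TRUE)
    for (i in seq_len(n_spots)) {
      zr <- z_lo[sy[i], sx[i]]:z_hi[sy[i], sx[i]]
      sz <- if (length(zr) > 1L) sample(zr, 1L) else zr
      yy <- max(1L, sy[i] - 1L):min(ny, sy[i] + 1L)
      xx <- max(1L, sx[i] - 1L):min(nx, sx[i] + 1L)
      nuc[sz, yy, xx] <- e$intensity
    }
    list(nuclei = voxel_grid(nuc, vs, "nuclei"),
         k10 = voxel_grid(k10, vs, "cytokeratin-10"),
         involucrin = voxel_grid(inv, vs, "involucrin"),
         truth = list(z_bottom = z_lo, z_top = z_hi,
                      thickness_um = matrix(nvox, ny, nx) * dz,
                      mask = binary_volume(slab, vs)))
  })
}

#' Tubular vessel phantom with exact axes and radii
#'
#' Rasterizes each tube as a solid capsule around its polyline axis in
#' physical micrometre space (a voxel is foreground when its centre lies
#' within `radius_um` of the axis), which is anisotropy-correct by
#' construction. The recorded truth volume fraction comes from the same
#' rasterization, never from a re-measurement.
#'
#' @param spec a [phantom_spec]; uses `shape_vox`, `voxel_size`, `vessels`.
#' @param blur_sigma_um optional Gaussian blur of the intensity channel
#'   (physical units) emulating the optical point-spread; the truth mask is
#'   never blurred.
#' @return List with `col4` (a [voxel_grid]) and `truth`: `mask`
#'   ([binary_volume]), `vf` (voxel-count fraction), `tubes` (input
#'   geometry), `analytic_volume_um3` (sum of cylinder volumes pi r^2 L
#'   over polyline length, end caps not included).
#' @export
make_vessel_phantom <- function(spec, blur_sigma_um = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_vox; vs <- spec$voxel_size
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  zc <- .axis_coords(nz, vs[1L]); yc <- .axis_coords(ny, vs[2L]); xc <- .axis_coords(nx, vs[3L])
  mask <- array(FALSE, d)
  intens <- array(0, d)
  analytic <- 0
  for (tube in spec$vessels) {
    r <- tube$radius_um
    if (r < max(vs) / 2)
      warning(sprintf("tube radius %.2f um below half the largest voxel dimension (%.2f um): unresolvable",
                      r, max(vs)))
    ti <- if (is.null(tube$intensity)) 1 else tube$intensity
    cp <- tube$control_points
    for (s in seq_len(nrow(cp) - 1L)) {
      P <- cp[s, ]; Q <- cp[s + 1L, ]
      analytic <- analytic + pi * r^2 * sqrt(sum((Q - P)^2))
      # bounding box in voxel indices, padded by r
      zr <- which(zc >= min(P[1L], Q[1L]) - r & zc <= max(P[1L], Q[1L]) + r)
      yr <- which(yc >= min(P[2L], Q[2L]) - r & yc <= max(P[2L], Q[2L]) + r)
      xr <- which(xc >= min(P[3L], Q[3L]) - r & xc <= max(P[3L], Q[3L]) + r)
      if (!length(zr) || !length(yr) || !length(xr)) next
      g <- expand.grid(z = zc[zr], y = yc[yr], x = xc[xr])
      v <- Q - P
      L2 <- sum(v^2)
      w <- cbind(g$z - P[1L], g$y - P[2L], g$x - P[3L])
      t <- if (L2 > 0) pmin(pmax(as.vector(w %*% v) / L2, 0), 1) else 0
      dist2 <- (w[, 1L] - t * v[1L])^2 + (w[, 2L] - t * v[2L])^2 + (w[, 3L] - t * v[3L])^2
      inside <- array(dist2 <= r^2, c(length(zr), length(yr), length(xr)))
      mask[zr, yr, xr] <- array(mask[zr, yr, xr], dim(inside)) | inside
      sub <- array(intens[zr, yr, xr], dim(inside))
      sub[inside] <- pmax(sub[inside], ti)
      intens[zr, yr, xr] <- sub
    }
  }
  if (blur_sigma_um > 0)
    intens <- array(.gauss_smooth_cpp(as.numeric(intens), d, blur_sigma_um / vs), d)
  list(col4 = voxel_grid(intens, vs, "collagen-IV"),
       truth = list(mask = binary_volume(mask, vs), vf = mean(mask),
                    tubes = spec$vessels, analytic_volume_um3 = analytic))
}

#' Regular grid of parallel tubes
#'
#' Convenience geometry builder: straight tubes along x, arranged on a
#' square (z, y) lattice with the given spacing, spanning the full volume.
#' Used to study how diffusion length grows with inter-vessel spacing.
#'
#' @param shape_vox,voxel_size volume geometry as in [phantom_spec].
#' @param spacing_um centre-to-centre tube spacing in z and y (um).
#' @param radius_um tube radius (um).
#' @param intensity tube intensity.
#' @return A list of tubes suitable for the `vessels` block of
#'   [phantom_spec].
#' @export
parallel_tubes <- function(shape_vox, voxel_size, spacing_um, radius_um,
                           intensity = 1) {
  ext <- shape_vox * voxel_size # (z, y, x) physical extent
  zs <- seq(spacing_um / 2, ext[1L], by = spacing_um)
  ys <- seq(spacing_um / 2, ext[2L], by = spacing_um)
  tubes <- list()
  for (z0 in zs) for (y0 in ys)
    tubes[[length(tubes) + 1L]] <- list(
      control_points = rbind(c(z0, y0, -2 * radius_um),
                             c(z0, y0, ext[3L] + 2 * radius_um)),
      radius_um = radius_um, intensity = intensity)
  tubes
}

#' Lipid droplet phantom with analytic sphere volumes
#'
#' Places `n` non-overlapping spheres (rejection sampling with bounded
#' retries) with radii drawn uniformly from `radius_range_um`, confined to
#' the physical z-interval `layer_z_range_um` (default: the basal half of
#' the volume). Droplet intensity is a spec parameter at fixed geometry, so
#' lipid loss can be emulated as an intensity reduction without moving a
#' single voxel.
#'
#' @param spec a [phantom_spec]; uses `shape_vox`, `voxel_size`, `droplets`,
#'   `seed`.
#' @return List with `bodipy` (a [voxel_grid]) and `truth`: `mask`
#'   ([binary_volume]), `vf`, `centers_um` (n x 3), `radii_um`,
#'   `analytic_volume_um3` (sum of 4/3 pi r^3).
#' @export
make_adipose_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_vox; vs <- spec$voxel_size; dr <- spec$droplets
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  ext <- d * vs
  zrange <- if (is.null(dr$layer_z_range_um)) c(ext[1L] / 2, ext[1L]) else dr$layer_z_range_um
  .with_seed(spec$seed + 1L, {
    n <- dr$n
    centers <- matrix(0, 0L, 3L)
    radii <- numeric(0)
    if (n > 0L) {
      max_try <- 2000L
      for (i in seq_len(n)) {
        placed <- FALSE
        for (t in seq_len(max_try)) {
          r <- runif(1L, dr$radius_range_um[1L], dr$radius_range_um[2L])
          cz <- runif(1L, max(zrange[1L] + r, r), min(zrange[2L] - r, ext[1L] - r))
          cy <- runif(1L, r, ext[2L] - r)
          cx <- runif(1L, r, ext[3L] - r)
          if (!is.finite(cz)) break
          if (nrow(centers) == 0L ||
              all(sqrt(rowSums((centers - matrix(c(cz, cy, cx), nrow(centers), 3L,
                                                 byrow = TRUE))^2)) > radii + r)) {
            centers <- rbind(centers, c(cz, cy, cx))
            radii <- c(radii, r)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place ", n, " non-overlapping droplets after bounded retries")
      }
    }
    zc <- .axis_coords(nz, vs[1L]); yc <- .axis_coords(ny, vs[2L]); xc <- .axis_coords(nx, vs[3L])
    mask <- array(FALSE, d)
    for (i in seq_len(nrow(centers))) {
      r <- radii[i]
      zr <- which(abs(zc - centers[i, 1L]) <= r)
      yr <- which(abs(yc - centers[i, 2L]) <= r)
      xr <- which(abs(xc - centers[i, 3L]) <= r)
      if (!length(zr) || !length(yr) || !length(xr)) next
      g <- expand.grid(z = zc[zr], y = yc[yr], x = xc[xr])
      inside <- array((g$z - centers[i, 1L])^2 + (g$y - centers[i, 2L])^2 +
                        (g$x - centers[i, 3L])^2 <= r^2,
                      c(length(zr), length(yr), length(xr)))
      mask[zr, yr, xr] <- array(mask[zr, yr, xr], dim(inside)) | inside
    }
    list(bodipy = voxel_grid(dr$intensity * mask, vs, "BODIPY"),
         truth = list(mask = binary_volume(mask, vs), vf = mean(mask),
                      centers_um = centers, radii_um = radii,
                      analytic_volume_um3 = sum(4 / 3 * pi * radii^3)))
  })
}

#' Add structured background and noise to a channel
#'
#' Adds, in order: a smooth linear background ramp (random in-plane
#' direction), sparse autofluorescent Gaussian blobs, and pixelwise
#' Gaussian noise; the result is clipped at zero. Seeded and deterministic:
#' the same (grid, noise, seed) always returns the same volume.
#'
#' Clipping a zero-mean Gaussian at zero leaves a half-normal-inflected
#' sample whose SD is `sqrt(1/2 - 1/(2*pi))` times the nominal sigma on an
#' empty background; tests of the noise moment correct by that factor.
#'
#' @param grid a [voxel_grid].
#' @param noise noise block as in [phantom_spec] (`gaussian_sd`,
#'   `background_ramp_amplitude`, `autofluor_blob_density` per 10^6 voxels,
#'   `blob_intensity`, `blob_sigma_um`).
#' @param seed integer seed.
#' @return A noisy [voxel_grid].
#' @export
apply_noise <- function(grid, noise = list(), seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  noise <- utils::modifyList(list(gaussian_sd = 0, background_ramp_amplitude = 0,
                                  autofluor_blob_density = 0, blob_intensity = 0.5,
                                  blob_sigma_um = 5), noise)
  if (any(unlist(noise[c("gaussian_sd", "background_ramp_amplitude",
                         "autofluor_blob_density")]) < 0))
    stop("noise parameters must be >= 0")
  d <- dim(grid$data); vs <- grid$voxel_size
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  .with_seed(seed, {
    out <- grid$data
    if (noise$background_ramp_amplitude > 0) {
      ang <- runif(1L, 0, 2 * pi)
      ry <- matrix(seq(0, 1, length.out = ny), ny, nx)
      rx <- matrix(seq(0, 1, length.out = nx), ny, nx, byrow = TRUE)
      ramp <- cos(ang) * rx + sin(ang) * ry
      ramp <- (ramp - min(ramp)) / max(diff(range(ramp)), .Machine$double.eps)
      out <- out + noise$background_ramp_amplitude *
        aperm(array(ramp, c(ny, nx, nz)), c(3L, 1L, 2L))
    }
    if (noise$autofluor_blob_density > 0) {
      k <- rpois(1L, noise$autofluor_blob_density * prod(d) / 1e6)
      if (k > 0) {
        blobs <- array(0, d)
        bz <- sample.int(nz, k, replace = TRUE)
        by <- sample.int(ny, k, replace = TRUE)
        bx <- sample.int(nx, k, replace = TRUE)
        for (i in seq_len(k)) blobs[bz[i], by[i], bx[i]] <- 1
        blobs <- array(.gauss_smooth_cpp(as.numeric(blobs), d,
                                         noise$blob_sigma_um / vs), d)
        if (max(blobs) > 0) blobs <- blobs / max(blobs)
        out <- out + noise$blob_intensity * blobs
      }
    }
    if (noise$gaussian_sd > 0)
      out <- out + rnorm(prod(d), 0, noise$gaussian_sd)
    voxel_grid(pmax(out, 0), vs, grid$channel)
  })
}

#' Exhaustive diffusion-length reference
#'
#' Brute-force twin of [diffusion_length]: the minimum centre-to-centre
#' distance from every tissue voxel to the vessel set is found by exhaustive
#' search (O(N_tissue x N_vessel), volumes capped at 48^3), and the same
#' linear-interpolation quantile convention is applied. Used as the exact
#' oracle the production distance transform must match.
#'
#' @param mask a non-empty [binary_volume].
#' @param voxel_size `(dz, dy, dx)` um; defaults to the mask's.
#' @param coverage quantile in (0, 1).
#' @return Diffusion length in micrometres.
#' @export
brute_force_rk <- function(mask, voxel_size = NULL, coverage = 0.90) {
  stopifnot(inherits(mask, "binary_volume"))
  d <- dim(mask$mask)
  if (prod(d) > 48^3) stop("volume too large for exhaustive search (> 48^3 voxels)")
  if (!any(mask$mask)) stop("empty vessel mask: distances undefined")
  if (all(mask$mask)) return(0)
  if (is.null(voxel_size)) voxel_size <- mask$voxel_size
  dist <- .brute_force_dist_cpp(as.logical(mask$mask), as.integer(d),
                                as.numeric(voxel_size))
  unname(quantile(dist[!mask$mask], coverage, names = FALSE, type = 7))
}

#' Composite five-channel skin-equivalent scene
#'
#' Stacks the three phantoms into one scene mimicking the layered geometry
#' of the culture: epidermal slab on top, vessel network in the mid
#' (dermal) region, lipid droplets in the basal (hypodermal) layer; noise is
#' applied per channel with channel-distinct seeds.
#'
#' @param spec a [phantom_spec].
#' @return List with `channels` (named [voxel_grid]s: `nuclei`, `k10`,
#'   `involucrin`, `col4`, `bodipy`) and `truth` (named truth lists of the
#'   three generators).
#' @export
avhse_scene <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  epi <- make_epidermis_phantom(spec)
  ves <- make_vessel_phantom(spec, blur_sigma_um = 1)
  adi <- make_adipose_phantom(spec)
  ch <- list(nuclei = epi$nuclei, k10 = epi$k10, involucrin = epi$involucrin,
             col4 = ves$col4, bodipy = adi$bodipy)
  ch <- mapply(function(g, i) apply_noise(g, spec$noise, spec$seed + 10L + i),
               ch, seq_along(ch), SIMPLIFY = FALSE)
  list(channels = ch,
       truth = list(epidermis = epi$truth, vessels = ves$truth,
                    adipose = adi$truth))
}
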