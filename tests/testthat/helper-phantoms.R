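# shared fixture builders and small oracles, all generated in code

grid3 <- function(data, vs = c(1, 1, 1), channel = "") {
  voxel_grid(data, voxel_size = vs, channel = channel)
}

# Dice overlap of two logical arrays
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# params for background-free synthetic volumes: no rolling-ball stage
params_no_bg <- function(...) {
  filter_params(rolling_ball_radius_px = NULL, disk_radius_px = 0L, ...)
}

# brute-force per-pixel window median with symmetric (reflect) padding;
# independent oracle for the plane-wise median filter
median_oracle <- function(m, r) {
  refl <- function(i, n) {
    while (any(i < 1L | i > n)) {
      i[i < 1L] <- 1L - i[i < 1L]
      i[i > n] <- 2L * n + 1L - i[i > n]
    }
    i
  }
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    ys <- refl(y + (-r:r), ny)
    xs <- refl(x + (-r:r), nx)
    out[y, x] <- median(m[ys, xs])
  }
  out
}

# axis-aligned digital cylinder along x (isotropic units)
cylinder_mask <- function(nz, ny, nx, cz, cy, r, x_range) {
  m <- array(FALSE, c(nz, ny, nx))
  for (z in seq_len(nz)) for (y in seq_len(ny))
    if ((z - cz)^2 + (y - cy)^2 <= r^2) m[z, y, x_range] <- TRUE
  m
}

# connected components of a skeleton point set under 26-adjacency
skeleton_components <- function(pts) {
  n <- nrow(pts)
  if (n == 0L) return(0L)
  lab <- integer(n)
  cur <- 0L
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  idx <- stats::setNames(seq_len(n), key)
  for (s in seq_len(n)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      i <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        j <- idx[paste(pts[i, 1] + dz, pts[i, 2] + dy, pts[i, 3] + dx)]
        if (!is.na(j) && lab[j] == 0L) { lab[j] <- cur; stack <- c(stack, j) }
      }
    }
  }
  cur
}
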