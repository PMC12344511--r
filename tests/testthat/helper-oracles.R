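# Independent brute-force evaluators used as oracles. Deliberately written
# as plain scalar-loop R, sharing no code with the package internals.

# trilinear interpolation at one 0-based voxel coordinate
tri_at <- function(vol, x, y, z, background = 0) {
  d <- dim(vol)
  if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 || z > d[3] - 1)
    return(background)
  i0 <- min(max(floor(x), 0), d[1] - 2)
  j0 <- min(max(floor(y), 0), d[2] - 2)
  k0 <- min(max(floor(z), 0), d[3] - 2)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  acc <- 0
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di == 1) fx else 1 - fx) * (if (dj == 1) fy else 1 - fy) *
      (if (dk == 1) fz else 1 - fz)
    acc <- acc + w * vol[i0 + di + 1, j0 + dj + 1, k0 + dk + 1]
  }
  acc
}

# Catmull-Rom interpolation at one 0-based voxel coordinate, written as
# nested 1D Horner-form basis evaluations (not the package's tensor loop)
cr1 <- function(p0, p1, p2, p3, t) {
  0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
           (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

cr_at <- function(vol, x, y, z, background = 0) {
  d <- dim(vol)
  if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 || z > d[3] - 1)
    return(background)
  i0 <- min(floor(x), d[1] - 2); j0 <- min(floor(y), d[2] - 2)
  k0 <- min(floor(z), d[3] - 2)
  cl <- function(i, n) min(max(i, 1), n)
  vz <- numeric(4)
  for (c_ in 0:3) {
    vy <- numeric(4)
    for (b in 0:3) {
      px <- vapply(0:3, function(a)
        vol[cl(i0 - 1 + a + 1, d[1]), cl(j0 - 1 + b + 1, d[2]),
            cl(k0 - 1 + c_ + 1, d[3])], numeric(1))
      vy[b + 1] <- cr1(px[1], px[2], px[3], px[4], x - i0)
    }
    vz[c_ + 1] <- cr1(vy[1], vy[2], vy[3], vy[4], y - j0)
  }
  cr1(vz[1], vz[2], vz[3], vz[4], z - k0)
}

# masked SSD term: 1/2 mean over region voxels of (moving(x+u) - fixed)^2
oracle_ssd <- function(u, fixed, moving, region, sampler = tri_at) {
  sp <- fixed$spacing
  idx <- which(region, arr.ind = TRUE)
  acc <- 0
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    mvv <- sampler(moving$data,
                   (i - 1) + u$vectors[i, j, k, 1] / sp[1],
                   (j - 1) + u$vectors[i, j, k, 2] / sp[2],
                   (k - 1) + u$vectors[i, j, k, 3] / sp[3])
    acc <- acc + (mvv - fixed$data[i, j, k])^2
  }
  acc / (2 * nrow(idx))
}

# curvature term: 1/2 mean over grid of sum_c (Lap u_c)^2, Neumann stencil
oracle_curvature <- function(u, spacing) {
  d <- dim(u$vectors)[1:3]
  at <- function(c_, i, j, k) {
    i <- min(max(i, 1), d[1]); j <- min(max(j, 1), d[2])
    k <- min(max(k, 1), d[3])
    u$vectors[i, j, k, c_]
  }
  acc <- 0
  for (c_ in 1:3) for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    lap <- (at(c_, i + 1, j, k) + at(c_, i - 1, j, k) - 2 * at(c_, i, j, k)) /
      spacing[1]^2 +
      (at(c_, i, j + 1, k) + at(c_, i, j - 1, k) - 2 * at(c_, i, j, k)) /
      spacing[2]^2 +
      (at(c_, i, j, k + 1) + at(c_, i, j, k - 1) - 2 * at(c_, i, j, k)) /
      spacing[3]^2
    acc <- acc + lap^2
  }
  acc / (2 * prod(d))
}

# surface term: mean over points of D(p + u(p))^2; points at voxel centres
oracle_surface <- function(u, points_world, dt_values, spacing) {
  acc <- 0
  for (r in seq_len(nrow(points_world))) {
    vox <- points_world[r, ] / spacing
    i <- round(vox[1]) + 1; j <- round(vox[2]) + 1; k <- round(vox[3]) + 1
    p <- vox + u$vectors[i, j, k, ] / spacing
    dval <- tri_at(dt_values, p[1], p[2], p[3])
    acc <- acc + dval^2
  }
  acc / nrow(points_world)
}

# brute-force Euclidean distance to a seed voxel set
oracle_edt <- function(seed_mask, spacing) {
  d <- dim(seed_mask)
  seeds <- which(seed_mask, arr.ind = TRUE)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    dx <- (seeds[, 1] - i) * spacing[1]
    dy <- (seeds[, 2] - j) * spacing[2]
    dz <- (seeds[, 3] - k) * spacing[3]
    out[i, j, k] <- sqrt(min(dx^2 + dy^2 + dz^2))
  }
  out
}
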