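# Shared numerical helpers: interpolation wrappers, discrete Laplacian,
# mm-metric morphology via the distance transform, pyramids, seeded RNG.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# 0-based fractional voxel indices of world points (n x 3, mm)
world_to_index <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`)
}

index_to_world <- function(idx, spacing, origin) {
  sweep(sweep(idx, 2, spacing, `*`), 2, origin, `+`)
}

# Trilinear (or nearest) sampling of a 3D array at 0-based voxel coords.
interp3 <- function(arr, idx, background = 0, nearest = FALSE, clamp = FALSE) {
  interp3_cpp(as.double(arr), as.integer(dim(arr)), idx,
              as.double(background), nearest, clamp)
}

# Value + exact gradient (per unit voxel index) of the trilinear interpolant.
interp3_grad <- function(arr, idx, background = 0, clamp = FALSE) {
  interp3_grad_cpp(as.double(arr), as.integer(dim(arr)), idx,
                   as.double(background), clamp)
}

# n x 3 matrix of the 0-based voxel indices of every grid point, fastest in x.
grid_index_matrix <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

# Clamped single-voxel shift of a 3D array along one axis (+1 or -1);
# replicated edges give zero-flux (Neumann) boundaries.
shift3 <- function(a, axis, dir) {
  n <- dim(a)[axis]
  ix <- if (dir > 0) c(seq(2L, n), n) else c(1L, seq(1L, n - 1L))
  switch(axis, a[ix, , , drop = FALSE], a[, ix, , drop = FALSE], a[, , ix, drop = FALSE])
}

# Spacing-aware 6-neighbour Laplacian with Neumann boundaries, units 1/mm^2.
laplacian3 <- function(a, spacing) {
  array(laplacian3_cpp(as.double(a), as.integer(dim(a)), as.double(spacing)),
        dim(a))
}

# Vector Laplacian applied componentwise to an X x Y x Z x 3 field.
laplacian_field <- function(u, spacing) {
  out <- u
  for (c_ in 1:3)
    out[, , , c_] <- laplacian3(u[, , , c_, drop = TRUE], spacing)
  out
}

# Separable [1,2,1]/4 smoothing (Neumann edges), applied per axis.
smooth3 <- function(a) {
  for (ax in 1:3)
    a <- (shift3(a, ax, 1) + 2 * a + shift3(a, ax, -1)) / 4
  a
}

# Surface voxels: mask voxels with a 6-neighbour outside the mask
# (out-of-grid neighbours count as outside).
mask_surface <- function(mask) {
  d <- dim(mask)
  inner <- array(TRUE, d)
  for (ax in 1:3) {
    inner <- inner & shift3(mask, ax, 1) & shift3(mask, ax, -1)
  }
  # clamped shifts replicate edges; force grid-boundary voxels to be surface
  inner[c(1, d[1]), , ] <- FALSE
  inner[, c(1, d[2]), ] <- FALSE
  inner[, , c(1, d[3])] <- FALSE
  mask & !inner
}

# Distance (mm) from the surface voxel set of a mask, everywhere on the grid.
surface_distance <- function(mask, spacing) {
  surf <- mask_surface(mask)
  if (!any(surf)) stop("surface_distance: mask has no surface voxels", call. = FALSE)
  array(edt3_cpp(as.logical(surf), as.integer(dim(mask)), as.double(spacing)),
        dim(mask))
}

dilate_mask <- function(mask, spacing, r_mm) {
  if (r_mm <= 0 || !any(mask)) return(mask)
  mask | (surface_distance(mask, spacing) <= r_mm)
}

erode_mask <- function(mask, spacing, r_mm) {
  if (r_mm <= 0 || !any(mask)) return(mask)
  mask & (surface_distance(mask, spacing) > r_mm)
}

#' Dice overlap coefficient between two binary masks
#' @param a,b logical arrays of identical shape.
#' @return `2|a & b| / (|a| + |b|)`.
#' @export
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

connected_components <- function(mask) {
  array(label6_cpp(as.logical(mask), as.integer(dim(mask))), dim(mask))
}

# One pyramid reduction: smooth then decimate by 2 (keeps sample 0, so the
# origin is unchanged and the spacing doubles).
downsample_array <- function(a, smooth = TRUE) {
  if (smooth) a <- smooth3(a)
  d <- dim(a)
  a[seq(1L, d[1], by = 2L), seq(1L, d[2], by = 2L), seq(1L, d[3], by = 2L),
    drop = FALSE]
}

downsample_mask <- function(m, threshold = 0.2) {
  downsample_array(array(as.double(m), dim(m))) > threshold
}
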