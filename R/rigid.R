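# Rigid alignment of the loaded scan to the unloaded scan, estimated from
# the tibial bone mask only, so subsequent motion is expressed relative to a
# fixed tibia. Parameterised by Euler angles about the canonical axes with
# the rotation centre at the tibia-mask centroid; fitted by Gauss-Newton on
# masked SSD over a coarse-to-fine image pyramid.

#' Rigid transform (Euler angles + translation about a centre)
#'
#' Maps fixed-image world coordinates to moving-image world coordinates:
#' `y = R (x - center) + center + translation`, with
#' `R = Rz(rz) Ry(ry) Rx(rx)`.
#'
#' @param rotation length-3 Euler angles in degrees about the x, y, z axes.
#' @param translation length-3 translation in mm.
#' @param center rotation centre in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  t <- structure(list(rotation = as.numeric(rotation),
                      translation = as.numeric(translation),
                      center = as.numeric(center)),
                 class = "rigid_transform")
  R <- rotation_matrix(t$rotation)
  stopifnot(max(abs(crossprod(R) - diag(3))) < 1e-8, abs(det(R) - 1) < 1e-8)
  t
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rotation (deg): ",
      paste(signif(x$rotation, 5), collapse = ", "),
      " | translation (mm): ", paste(signif(x$translation, 5), collapse = ", "),
      "\n  centre (mm): ", paste(signif(x$center, 5), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

rot_axis <- function(angle_rad, axis) {
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  m <- diag(3)
  ij <- switch(axis, x = c(2, 3), y = c(3, 1), z = c(1, 2))
  m[ij[1], ij[1]] <- c_; m[ij[2], ij[2]] <- c_
  m[ij[1], ij[2]] <- -s_; m[ij[2], ij[1]] <- s_
  m
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  rot_axis(r[3], "z") %*% rot_axis(r[2], "y") %*% rot_axis(r[1], "x")
}

# Euler angles (deg) of R = Rz Ry Rx
euler_from_matrix <- function(R) {
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold everything into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  c(rx, ry, rz) * 180 / pi
}

#' Apply a rigid transform to world points
#' @param transform a [rigid_transform].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, pts) {
  R <- rotation_matrix(transform$rotation)
  ctr <- transform$center
  sweep(sweep(pts, 2, ctr, `-`) %*% t(R), 2, ctr + transform$translation, `+`)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform].
#' @return The inverse [rigid_transform] (same rotation centre).
#' @export
rigid_inverse <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  # y = R (x - c) + c + t  =>  x = R' (y - c - t) + c
  #   = R'(y - c) + c - R' t
  rigid_transform(rotation = euler_from_matrix(t(R)),
                  translation = as.numeric(-t(R) %*% transform$translation),
                  center = transform$center)
}

#' Compose two rigid transforms
#' @param a,b [rigid_transform]s; the result applies `b` first, then `a`.
#' @return A [rigid_transform] with the centre of `a`.
#' @export
rigid_compose <- function(a, b) {
  Ra <- rotation_matrix(a$rotation); Rb <- rotation_matrix(b$rotation)
  # a(b(x)) = Ra (Rb (x - cb) + cb + tb - ca) + ca + ta
  R <- Ra %*% Rb
  ca <- a$center; cb <- b$center
  # a(b(x)) = R (x - ca) + R (ca - cb) + Ra (cb + tb - ca) + ca + ta
  t_new <- as.numeric(R %*% (ca - cb)) +
    as.numeric(Ra %*% (cb + b$translation - ca)) + a$translation
  rigid_transform(euler_from_matrix(R), t_new, ca)
}

#' Resample a volume or structure set through a rigid transform
#'
#' Produces the moving image expressed on the reference grid:
#' `out(x) = moving(T(x))`. Intensity volumes are trilinearly interpolated;
#' masks use nearest-neighbour sampling so they stay binary.
#'
#' @param moving a [knee_volume] or [structure_set].
#' @param transform a [rigid_transform] mapping reference to moving
#'   coordinates.
#' @param reference_grid a [knee_volume] (or any object carrying `dim`,
#'   `spacing`, `origin`) defining the output grid; defaults to the moving
#'   grid.
#' @param background intensity for out-of-grid samples.
#' @param interpolation `"cubic"` (Catmull-Rom, the default for intensity
#'   volumes: its output is interpolated again by the deformable stage, and
#'   a second trilinear pass would blur the thin meniscal structures) or
#'   `"linear"`.
#' @return Object of the same type as `moving`, on the reference grid.
#' @export
resample_rigid <- function(moving, transform, reference_grid = moving,
                           background = 0,
                           interpolation = c("cubic", "linear")) {
  interpolation <- match.arg(interpolation)
  g <- grid_meta(reference_grid)
  if (is.null(g$spacing)) stop("resample_rigid: reference grid metadata ",
                               "(spacing/origin) is incomplete", call. = FALSE)
  d <- g$dim[1:3]
  world <- index_to_world(grid_index_matrix(d), g$spacing, g$origin)
  tgt <- transform_points(transform, world)
  if (inherits(moving, "knee_volume")) {
    tgt_idx <- world_to_index(tgt, moving$spacing, moving$origin)
    out <- if (interpolation == "cubic")
      interp3_cubic_cpp(as.double(moving$data), as.integer(dim(moving$data)),
                        tgt_idx, as.double(background))
    else interp3(moving$data, tgt_idx, background = background)
    return(knee_volume(array(out, d), g$spacing, g$origin))
  }
  if (inherits(moving, "structure_set")) {
    tgt_idx <- world_to_index(tgt, moving$spacing, moving$origin)
    # linear-interpolated indicator thresholded at 0.5: keeps the mask
    # binary while tracking the boundary at sub-voxel accuracy (nearest-
    # neighbour sampling would snap the set to whole-voxel shifts)
    masks <- lapply(moving$masks, function(m) {
      array(interp3(array(as.double(m), dim(m)), tgt_idx, background = 0),
            d) > 0.5
    })
    return(structure_set(masks, g$spacing, g$origin))
  }
  stop("resample_rigid: unsupported input type", call. = FALSE)
}

#' Re-express a rigid transform about a different rotation centre
#'
#' The mapping is unchanged; only the (rotation centre, translation)
#' parameterisation changes. Useful for comparing transforms estimated with
#' different centres component by component.
#'
#' @param transform a [rigid_transform].
#' @param center new rotation centre (mm).
#' @return An equivalent [rigid_transform] with the requested centre.
#' @export
rigid_with_center <- function(transform, center) {
  R <- rotation_matrix(transform$rotation)
  c_old <- transform$center
  t_new <- as.numeric(R %*% (center - c_old)) + c_old +
    transform$translation - center
  rigid_transform(transform$rotation, t_new, center)
}

# analytic derivative of the rotation matrix wrt one Euler angle (radians)
rotation_matrix_deriv <- function(rot_rad, which) {
  gen <- function(axis) {
    # d/da Raxis(a) = G %*% Raxis(a) with G the skew generator
    switch(axis,
           x = matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3),
           y = matrix(c(0, 0, -1, 0, 0, 0, 1, 0, 0), 3, 3),
           z = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3))
  }
  Rx <- rot_axis(rot_rad[1], "x"); Ry <- rot_axis(rot_rad[2], "y")
  Rz <- rot_axis(rot_rad[3], "z")
  switch(which,
         Rz %*% Ry %*% (gen("x") %*% Rx),
         Rz %*% (gen("y") %*% Ry) %*% Rx,
         (gen("z") %*% Rz) %*% Ry %*% Rx)
}

#' Masked rigid registration restricted to the tibial bone
#'
#' Estimates the rigid transform minimising the sum of squared intensity
#' differences between the fixed image and the resampled moving image over
#' the (dilated) tibia mask, coarse-to-fine over an image pyramid with a
#' Gauss-Newton optimiser and Armijo line search. Deterministic for fixed
#' inputs.
#'
#' @param fixed,moving [knee_volume]s on a common grid layout.
#' @param tibia_mask logical 3D array on the fixed grid (non-empty).
#' @param levels pyramid levels (coarsest has spacing `2^(levels-1)` times
#'   the original).
#' @param max_iter Gauss-Newton iterations per level.
#' @param tol relative objective-decrease stopping threshold.
#' @param dilate_voxels dilation of the mask (in voxels of minimum spacing)
#'   to stabilise gradients at the bone boundary.
#' @return A [rigid_transform]; attributes `objective` (final masked mean
#'   squared difference) and `converged`. A warning is issued if the finest
#'   level hits `max_iter` without meeting `tol`.
#' @export
register_rigid_masked <- function(fixed, moving, tibia_mask, levels = 3,
                                  max_iter = 30, tol = 1e-6, dilate_voxels = 1) {
  stopifnot(inherits(fixed, "knee_volume"), inherits(moving, "knee_volume"))
  if (!any(tibia_mask)) stop("register_rigid_masked: tibia mask is empty",
                             call. = FALSE)
  if (!identical(dim(tibia_mask), dim(fixed$data)))
    stop_grid_mismatch(structure(list(data = array(0, dim(tibia_mask)),
                                      spacing = fixed$spacing,
                                      origin = fixed$origin),
                                 class = "knee_volume"), fixed,
                       "tibia mask and fixed image")
  mask <- dilate_mask(tibia_mask, fixed$spacing,
                      dilate_voxels * min(fixed$spacing))
  ctr <- colMeans(mask_world_coords(mask, fixed$spacing, fixed$origin))

  pyr <- list(list(fixed = fixed, moving = moving, mask = mask))
  for (l in seq_len(levels - 1)) {
    prev <- pyr[[l]]
    fm <- downsample_mask(prev$mask)
    if (sum(fm) < 50) break
    pyr[[l + 1]] <- list(
      fixed = knee_volume(downsample_array(prev$fixed$data),
                          2 * prev$fixed$spacing, prev$fixed$origin),
      moving = knee_volume(downsample_array(prev$moving$data),
                           2 * prev$moving$spacing, prev$moving$origin),
      mask = fm)
  }

  theta <- rep(0, 6) # rx, ry, rz (rad), tx, ty, tz (mm)
  converged <- TRUE
  obj <- NA_real_
  for (l in rev(seq_along(pyr))) {
    lv <- pyr[[l]]
    fit <- rigid_gn_level(theta, lv$fixed, lv$moving, lv$mask, ctr,
                          max_iter = max_iter, tol = tol)
    theta <- fit$theta
    obj <- fit$objective
    if (l == 1) converged <- fit$converged
  }
  if (!converged)
    warning("register_rigid_masked: finest level stopped at max_iter; ",
            "returning best transform (objective ", signif(obj, 6), ")")
  out <- rigid_transform(rotation = theta[1:3] * 180 / pi,
                         translation = theta[4:6], center = ctr)
  attr(out, "objective") <- obj
  attr(out, "converged") <- converged
  out
}

rigid_objective <- function(theta, fixed_vals, world, moving, ctr) {
  tr <- list(rotation = theta[1:3] * 180 / pi, translation = theta[4:6],
             center = ctr)
  tgt <- transform_points(tr, world)
  idx <- world_to_index(tgt, moving$spacing, moving$origin)
  mv <- interp3(moving$data, idx, clamp = TRUE)
  r <- mv - fixed_vals
  list(value = mean(r^2) / 2, residual = r, idx = idx)
}

rigid_gn_level <- function(theta, fixed, moving, mask, ctr, max_iter, tol) {
  world <- mask_world_coords(mask, fixed$spacing, fixed$origin)
  fixed_vals <- fixed$data[mask]
  xc <- sweep(world, 2, ctr, `-`)
  n <- nrow(world)
  cur <- rigid_objective(theta, fixed_vals, world, moving, ctr)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    vg <- interp3_grad(moving$data, cur$idx, clamp = TRUE)
    g_mm <- sweep(vg[, 2:4, drop = FALSE], 2, moving$spacing, `/`)
    J <- matrix(0, n, 6)
    for (p in 1:3) {
      dR <- rotation_matrix_deriv(theta[1:3], p)
      J[, p] <- rowSums(g_mm * (xc %*% t(dR)))
    }
    J[, 4:6] <- g_mm
    H <- crossprod(J) / n
    b <- -as.numeric(crossprod(J, cur$residual)) / n
    H <- H + diag(1e-9 * max(diag(H)) + 1e-12, 6)
    delta <- tryCatch(solve(H, b), error = function(e) b)
    gdot <- -sum(b * delta)
    if (!is.finite(gdot) || gdot >= 0) delta <- b
    s <- 1
    new <- NULL
    for (ls in 1:25) {
      cand <- rigid_objective(theta + s * delta, fixed_vals, world, moving, ctr)
      if (is.finite(cand$value) &&
          cand$value <= cur$value - 1e-4 * s * abs(gdot)) { new <- cand; break }
      s <- s / 2
    }
    if (is.null(new)) { converged <- TRUE; break }
    theta <- theta + s * delta
    dec <- (cur$value - new$value) / max(cur$value, .Machine$double.eps)
    cur <- new
    if (dec < tol) { converged <- TRUE; break }
  }
  list(theta = theta, objective = cur$value, converged = converged)
}
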