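# Variational registration energy: masked SSD similarity + curvature
# regulariser + surface-distance penalty. Each term is normalised to a
# per-voxel / per-point mean so the weights transfer across resolutions:
#
#   J(u) = 1/2 mean_{x in M} (Mv(x + u(x)) - F(x))^2
#        + alpha * 1/2 mean_grid sum_c (Lap u_c)^2
#        + beta  * mean_{p in S} D(p + u(p))^2
#
# M is the union of both fixed meniscus masks dilated by a few mm, S the
# surface voxel set of the fixed menisci, and D the Euclidean distance
# transform of the moving meniscus contour, so the penalty measures the
# point-to-point distance between the displaced fixed meniscal surface and
# the moving meniscal surface.

#' Registration configuration
#'
#' Tuning parameters of the deformable registration energy and its
#' multilevel matrix-free Gauss-Newton solver.
#'
#' @param alpha curvature regulariser weight (> 0; the energy is ill-posed
#'   without it).
#' @param beta surface-distance penalty weight (>= 0).
#' @param levels pyramid levels (>= 1); each level halves the resolution.
#' @param max_iter maximum Gauss-Newton iterations per level.
#' @param cg_max_iter maximum conjugate-gradient iterations per Gauss-Newton
#'   step.
#' @param cg_tol relative residual tolerance of the CG solve.
#' @param step_tol relative objective-decrease stopping threshold.
#' @param ssd_region_dilation_mm dilation (mm) of the fixed meniscal masks
#'   defining the SSD region.
#' @param presmooth apply one binomial smoothing pass to both images before
#'   building the pyramid (noise tempering for the finest level).
#' @param image_interpolation interpolation model for sampling the moving
#'   image inside the similarity term: `"cubic"` (Catmull-Rom; C1, smooth
#'   analytic gradients) or `"linear"` (trilinear).
#' @param armijo_c1,armijo_rho,armijo_max Armijo line-search parameters.
#' @param avg_per_voxel_norm report the per-scope Avg as the mean of
#'   per-voxel displacement norms instead of the norm of the mean vector
#'   (see [summarize_motion()]).
#' @return A list of class `registration_control`.
#' @export
registration_control <- function(alpha = 1.0, beta = 0.3, levels = 3,
                                 max_iter = 50, cg_max_iter = 30,
                                 cg_tol = 1e-2, step_tol = 1e-4,
                                 ssd_region_dilation_mm = 2,
                                 presmooth = FALSE,
                                 image_interpolation = c("cubic", "linear"),
                                 armijo_c1 = 1e-4, armijo_rho = 0.5,
                                 armijo_max = 25,
                                 avg_per_voxel_norm = FALSE) {
  image_interpolation <- match.arg(image_interpolation)
  if (alpha <= 0) stop("registration_control: alpha must be > 0", call. = FALSE)
  if (beta < 0) stop("registration_control: beta must be >= 0", call. = FALSE)
  if (levels < 1) stop("registration_control: levels must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, levels = as.integer(levels),
                 max_iter = as.integer(max_iter),
                 cg_max_iter = as.integer(cg_max_iter), cg_tol = cg_tol,
                 step_tol = step_tol,
                 ssd_region_dilation_mm = ssd_region_dilation_mm,
                 presmooth = presmooth,
                 image_interpolation = image_interpolation,
                 armijo_c1 = armijo_c1, armijo_rho = armijo_rho,
                 armijo_max = as.integer(armijo_max),
                 avg_per_voxel_norm = avg_per_voxel_norm),
            class = "registration_control")
}

#' Euclidean distance map of a mask contour
#'
#' Distance in mm from every grid voxel to the nearest surface voxel of the
#' mask (mask voxels with at least one 6-neighbour outside the mask), exact
#' for the anisotropic grid metric.
#'
#' @param mask non-empty logical 3D array.
#' @param spacing voxel size in mm.
#' @param origin world origin in mm.
#' @return An object of class `distance_map` with elements `values`
#'   (3D array, mm), `spacing`, `origin`.
#' @export
contour_distance_map <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (!any(mask)) stop("contour_distance_map: mask is empty", call. = FALSE)
  structure(list(values = surface_distance(mask, spacing),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "distance_map")
}

# Internal state shared by the objective evaluation and the GN operator.
# region: logical array; surface: list of components, each with `points`
# (n x 3 world mm) and `dt` (distance_map of the matching moving contour).
# pre_transform: optional rigid transform composed into the moving-image
# sampling, M(T(x + u(x))), so the loaded scan is never resampled twice.
objective_state <- function(fixed, moving, region, surface, control,
                            pre_transform = NULL) {
  if (is.null(pre_transform) && !same_grid(fixed, moving))
    stop_grid_mismatch(fixed, moving, "fixed and moving images")
  if (!any(region)) stop("evaluate_objective: SSD region is empty", call. = FALSE)
  d <- dim(fixed$data)
  ridx <- which(region)
  rsub <- which(region, arr.ind = TRUE) - 1
  surf <- lapply(surface, function(s) {
    vox <- world_to_index(s$points, fixed$spacing, fixed$origin)
    lin <- as.integer(round(vox[, 1])) +
      dim(fixed$data)[1] * (as.integer(round(vox[, 2])) +
                              dim(fixed$data)[2] * as.integer(round(vox[, 3]))) + 1L
    list(vox = vox, lin = lin, dt = s$dt)
  })
  list(fixed = fixed, moving = moving, d = d, region_lin = ridx,
       region_idx = rsub,
       region_world = index_to_world(rsub, fixed$spacing, fixed$origin),
       fixed_vals = fixed$data[ridx], surf = surf, control = control,
       pre = pre_transform,
       pre_rot = if (!is.null(pre_transform))
         rotation_matrix(pre_transform$rotation))
}

# Evaluate the energy (and optionally its gradient and the pointwise
# Jacobian data needed by the Gauss-Newton operator).
objective_core <- function(u, st, want_gradient = FALSE) {
  ctl <- st$control
  d <- st$d
  n_grid <- prod(d)
  sp <- st$fixed$spacing
  # --- SSD over the meniscal region
  ur <- matrix(u, ncol = 3)[st$region_lin, , drop = FALSE]
  if (is.null(st$pre)) {
    idx <- st$region_idx + sweep(ur, 2, sp, `/`)
  } else {
    idx <- world_to_index(transform_points(st$pre, st$region_world + ur),
                          st$moving$spacing, st$moving$origin)
  }
  n_ssd <- length(st$region_lin)
  vg <- if (identical(ctl$image_interpolation, "cubic"))
    interp3_cubic_grad_cpp(as.double(st$moving$data),
                           as.integer(dim(st$moving$data)), idx, 0)
  else interp3_grad(st$moving$data, idx, background = 0, clamp = FALSE)
  r_ssd <- vg[, 1] - st$fixed_vals
  ssd <- mean(r_ssd^2) / 2
  # --- curvature
  Lu <- laplacian_field(u, sp)
  curv <- sum(Lu^2) / (2 * n_grid)
  # --- surface penalty
  surf_val <- 0
  n_pts <- 0L
  surf_data <- list()
  for (s in st$surf) {
    usr <- matrix(u, ncol = 3)[s$lin, , drop = FALSE]
    pidx <- s$vox + sweep(usr, 2, sp, `/`)
    dg <- interp3_grad(s$dt$values, pidx, background = 0, clamp = TRUE)
    surf_val <- surf_val + sum(dg[, 1]^2)
    n_pts <- n_pts + nrow(pidx)
    surf_data[[length(surf_data) + 1]] <-
      list(lin = s$lin, dist = dg[, 1],
           grad = sweep(dg[, 2:4, drop = FALSE], 2, sp, `/`))
  }
  surf_term <- if (n_pts > 0) surf_val / n_pts else 0
  out <- list(ssd_term = ssd, curvature_term = curv, surface_term = surf_term,
              total = ssd + ctl$alpha * curv + ctl$beta * surf_term,
              n_ssd_voxels = n_ssd, n_surface_points = n_pts)
  if (!want_gradient) return(out)
  g_mm <- sweep(vg[, 2:4, drop = FALSE], 2, st$moving$spacing, `/`)
  # chain rule through the composed rigid map: d/dx M(T(x)) = R' grad M
  if (!is.null(st$pre)) g_mm <- g_mm %*% st$pre_rot
  grad <- array(0, c(d, 3))
  gm <- matrix(grad, ncol = 3)
  gm[st$region_lin, ] <- (r_ssd / n_ssd) * g_mm
  grad <- array(gm, c(d, 3)) + ctl$alpha / n_grid * laplacian_field(Lu, sp)
  if (ctl$beta > 0 && n_pts > 0) {
    gm <- matrix(grad, ncol = 3)
    for (sd_ in surf_data)
      gm[sd_$lin, ] <- gm[sd_$lin, ] +
        ctl$beta * (2 / n_pts) * sd_$dist * sd_$grad
    grad <- array(gm, c(d, 3))
  }
  out$gradient <- grad
  out$ssd_grad_mm <- g_mm
  out$surf_data <- surf_data
  out
}

#' Evaluate the registration energy
#'
#' Computes the three energy terms of the variational registration at a
#' given displacement field, reported separately and combined as
#' `total = ssd_term + alpha * curvature_term + beta * surface_term`.
#'
#' @param u a [deformation_field] on the fixed grid.
#' @param fixed,moving [knee_volume]s on a common grid.
#' @param region logical 3D array: voxels entering the SSD term (the
#'   meniscal region).
#' @param surface_points n x 3 matrix of world coordinates (mm) of fixed
#'   meniscal surface points (expected at voxel centres), or a list of such
#'   matrices, one per meniscus.
#' @param surface_dt [contour_distance_map()] of the moving meniscus contour
#'   (or a list matching `surface_points`).
#' @param control a [registration_control].
#' @return A list (`objective_breakdown`) with `total`, `ssd_term`,
#'   `curvature_term`, `surface_term`, `n_ssd_voxels`, `n_surface_points`.
#' @export
evaluate_objective <- function(u, fixed, moving, region, surface_points,
                               surface_dt, control = registration_control()) {
  stopifnot(inherits(u, "deformation_field"))
  if (!same_grid(u, fixed)) stop_grid_mismatch(u, fixed, "field and fixed image")
  surface <- normalize_surface(surface_points, surface_dt)
  st <- objective_state(fixed, moving, region, surface, control)
  out <- objective_core(u$vectors, st, want_gradient = FALSE)
  structure(out[c("total", "ssd_term", "curvature_term", "surface_term",
                  "n_ssd_voxels", "n_surface_points")],
            class = "objective_breakdown")
}

normalize_surface <- function(surface_points, surface_dt) {
  if (is.null(surface_points)) return(list())
  if (is.matrix(surface_points)) {
    surface_points <- list(surface_points)
    surface_dt <- list(surface_dt)
  }
  Map(function(p, dtm) {
    stopifnot(inherits(dtm, "distance_map"))
    list(points = p, dt = dtm)
  }, surface_points, surface_dt)
}

# objective gradient entry point used by tests (finite-difference checks)
objective_gradient <- function(u, fixed, moving, region, surface_points,
                               surface_dt, control = registration_control()) {
  surface <- normalize_surface(surface_points, surface_dt)
  st <- objective_state(fixed, moving, region, surface, control)
  objective_core(u$vectors, st, want_gradient = TRUE)
}
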