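# Matrix-free Gauss-Newton solver for the registration energy, and the
# multilevel coarse-to-fine driver. The Gauss-Newton normal equations
#
#   (J_d' J_d / |M| + alpha/N Lap'Lap + 2 beta/|S| J_s' J_s) delta = -grad J
#
# are solved by conjugate gradients applying each operator block on the fly
# (pointwise 3x3 blocks for the data and surface terms, two Laplacian sweeps
# for the regulariser); no matrix is ever assembled. Steps are globalised by
# Armijo backtracking, so the accepted objective sequence never increases.

gn_operator <- function(ev, st) {
  ctl <- st$control
  sp <- st$fixed$spacing
  n_grid <- prod(st$d)
  n_ssd <- length(st$region_lin)
  g_mm <- ev$ssd_grad_mm
  # Levenberg-style damping at the scale of the data-block diagonal keeps
  # steps bounded along directions the residuals barely constrain
  damp <- 1e-2 * mean(rowSums(g_mm^2)) / n_ssd + 1e-12
  function(v) {
    vm <- matrix(v, ncol = 3)
    out <- ctl$alpha / n_grid * laplacian_field(laplacian_field(v, sp), sp)
    om <- matrix(out, ncol = 3)
    vr <- vm[st$region_lin, , drop = FALSE]
    om[st$region_lin, ] <- om[st$region_lin, ] +
      (rowSums(g_mm * vr) / n_ssd) * g_mm
    if (ctl$beta > 0) {
      n_pts <- ev$n_surface_points
      for (sd_ in ev$surf_data) {
        vs <- vm[sd_$lin, , drop = FALSE]
        om[sd_$lin, ] <- om[sd_$lin, ] +
          ctl$beta * (2 / n_pts) * rowSums(sd_$grad * vs) * sd_$grad
      }
    }
    array(om, dim(v)) + damp * v
  }
}

cg_solve <- function(apply_A, b, max_iter, tol) {
  x <- array(0, dim(b))
  r <- b
  p <- r
  rs <- sum(r * r)
  b_norm <- sqrt(rs)
  if (b_norm == 0) return(list(x = x, ok = TRUE))
  for (it in seq_len(max_iter)) {
    Ap <- apply_A(p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) return(list(x = x, ok = it > 1))
    a <- rs / pAp
    x <- x + a * p
    r <- r - a * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) <= tol * b_norm) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, ok = TRUE)
}

#' Gauss-Newton minimisation of the registration energy at one level
#'
#' Iterates `u <- u + s * delta`, with `delta` from a matrix-free
#' conjugate-gradient solve of the Gauss-Newton normal equations and the
#' step length `s` from Armijo backtracking. Stops when the relative
#' objective decrease falls below `control$step_tol` or `control$max_iter`
#' is reached. If the CG direction is not a descent direction the step falls
#' back to steepest descent.
#'
#' @param u0 a [deformation_field] starting value on the fixed grid.
#' @param fixed,moving [knee_volume]s on a common grid.
#' @param region logical 3D array of SSD voxels.
#' @param surface_points,surface_dt as in [evaluate_objective()].
#' @param control a [registration_control].
#' @return A [deformation_field] with attribute `trace`: a data frame with
#'   one row per accepted iterate (`iteration`, `total`, `ssd`, `curvature`,
#'   `surface`, `step_size`).
#' @export
gauss_newton_solve <- function(u0, fixed, moving, region, surface_points,
                               surface_dt, control = registration_control(),
                               pre_transform = NULL) {
  stopifnot(inherits(u0, "deformation_field"))
  surface <- normalize_surface(surface_points, surface_dt)
  st <- objective_state(fixed, moving, region, surface, control, pre_transform)
  u <- u0$vectors
  ev <- objective_core(u, st, want_gradient = TRUE)
  if (!is.finite(ev$total))
    stop("gauss_newton_solve: non-finite objective at iteration 0", call. = FALSE)
  trace <- data.frame(iteration = 0L, total = ev$total, ssd = ev$ssd_term,
                      curvature = ev$curvature_term, surface = ev$surface_term,
                      step_size = NA_real_)
  for (it in seq_len(control$max_iter)) {
    sol <- cg_solve(gn_operator(ev, st), -ev$gradient,
                    control$cg_max_iter, control$cg_tol)
    delta <- sol$x
    gdot <- sum(ev$gradient * delta)
    if (!sol$ok || !is.finite(gdot) || gdot >= 0) {
      delta <- -ev$gradient
      gdot <- -sum(ev$gradient^2)
    }
    if (gdot == 0) break
    s <- 1
    accepted <- NULL
    for (ls in seq_len(control$armijo_max)) {
      cand_u <- u + s * delta
      cand <- objective_core(cand_u, st, want_gradient = FALSE)
      if (is.finite(cand$total) &&
          cand$total <= ev$total + control$armijo_c1 * s * gdot) {
        accepted <- cand_u
        break
      }
      s <- s * control$armijo_rho
    }
    if (is.null(accepted)) break
    u <- accepted
    prev_total <- ev$total
    ev <- objective_core(u, st, want_gradient = TRUE)
    if (!is.finite(ev$total))
      stop("gauss_newton_solve: non-finite objective at iteration ", it,
           call. = FALSE)
    trace <- rbind(trace, data.frame(iteration = it, total = ev$total,
                                     ssd = ev$ssd_term,
                                     curvature = ev$curvature_term,
                                     surface = ev$surface_term, step_size = s))
    if ((prev_total - ev$total) / max(prev_total, .Machine$double.eps) <
        control$step_tol) break
  }
  out <- deformation_field(u, fixed$spacing, fixed$origin)
  attr(out, "trace") <- trace
  out
}

# crop all level inputs to a bounding box around the meniscal regions; the
# returned field is re-embedded on the full grid (zero outside the box)
meniscal_bounding_box <- function(fixed_structures, moving_structures,
                                  spacing, margin_mm) {
  m <- fixed_structures$masks$medial_meniscus |
    fixed_structures$masks$lateral_meniscus |
    moving_structures$masks$medial_meniscus |
    moving_structures$masks$lateral_meniscus
  sub <- which(m, arr.ind = TRUE)
  pad <- ceiling(margin_mm / spacing)
  d <- dim(m)
  lo <- pmax(apply(sub, 2, min) - pad, 1)
  hi <- pmin(apply(sub, 2, max) + pad, d)
  list(lo = lo, hi = hi)
}

crop_box <- function(arr, box) {
  arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
      drop = FALSE]
}

#' Multilevel deformable registration of the meniscal region
#'
#' Estimates the dense meniscal displacement field between rigidly
#' pre-aligned unloaded (fixed) and loaded (moving) scans. Builds an
#' image/mask pyramid (factor 2 per level with pre-smoothing), solves the
#' Gauss-Newton problem coarse to fine, and prolongates the millimetre-valued
#' field between levels by trilinear interpolation. The SSD region is the
#' union of the fixed meniscal masks dilated by
#' `control$ssd_region_dilation_mm`; the surface penalty couples the fixed
#' meniscal surface voxels of each meniscus with the distance transform of
#' the corresponding moving meniscus contour. For efficiency the problem is
#' solved on a bounding box around the menisci; the returned field is zero
#' outside it (vectors outside the menisci are cropped before analysis
#' anyway).
#'
#' @param fixed,moving [knee_volume]s on a common grid (moving already
#'   resampled by the rigid stage), unless `pre_transform` is given, in
#'   which case `moving` is the loaded scan on its native grid.
#' @param fixed_structures,moving_structures [structure_set]s on the fixed
#'   grid (moving structures already rigidly aligned).
#' @param control a [registration_control].
#' @param pre_transform optional [rigid_transform] composed into the
#'   moving-image sampling, `M(T(x + u(x)))`: avoids resampling the loaded
#'   scan a second time, which blurs the thin meniscal structures.
#' @return A [deformation_field] on the fixed grid with attribute `trace`
#'   (columns `level`, `iteration`, `total`, `ssd`, `curvature`, `surface`,
#'   `step_size`).
#' @export
register_multilevel <- function(fixed, moving, fixed_structures,
                                moving_structures,
                                control = registration_control(),
                                pre_transform = NULL) {
  stopifnot(inherits(fixed, "knee_volume"), inherits(moving, "knee_volume"))
  if (is.null(pre_transform) && !same_grid(fixed, moving))
    stop_grid_mismatch(fixed, moving, "fixed and moving images")
  if (!same_grid(fixed, fixed_structures))
    stop_grid_mismatch(fixed, fixed_structures, "fixed image and structures")
  if (!same_grid(fixed, moving_structures))
    stop_grid_mismatch(fixed, moving_structures, "fixed image and moving structures")

  full_dim <- dim(fixed$data)
  box <- meniscal_bounding_box(fixed_structures, moving_structures,
                               fixed$spacing,
                               margin_mm = control$ssd_region_dilation_mm + 4)
  origin_box <- fixed$origin + (box$lo - 1) * fixed$spacing
  fx <- knee_volume(crop_box(fixed$data, box), fixed$spacing, origin_box)
  mv <- if (is.null(pre_transform))
    knee_volume(crop_box(moving$data, box), fixed$spacing, origin_box)
  else moving # native grid; sampled through pre_transform, no crop
  fmasks <- lapply(fixed_structures$masks[MENISCUS_NAMES], crop_box, box = box)
  mmasks <- lapply(moving_structures$masks[MENISCUS_NAMES], crop_box, box = box)

  # normalise the intensity scale so the per-voxel energy weights are
  # intensity-unit independent: unit SD of the fixed image over the region
  region0 <- dilate_mask(fmasks$medial_meniscus | fmasks$lateral_meniscus,
                         fixed$spacing, control$ssd_region_dilation_mm)
  iscale <- stats::sd(fx$data[region0])
  if (!is.finite(iscale) || iscale <= 0) iscale <- 1
  # the curvature term is a per-grid-voxel mean: solving on the cropped box
  # must keep the same energy density as the full input grid, so alpha is
  # rescaled by the domain-size ratio
  control$alpha <- control$alpha * prod(dim(fx$data)) / prod(full_dim)
  # one binomial smoothing pass tempers noise and widens the basin of the
  # piecewise-linear image model at the finest level
  fx$data <- if (isTRUE(control$presmooth)) smooth3(fx$data / iscale)
             else fx$data / iscale
  mv$data <- if (isTRUE(control$presmooth)) smooth3(mv$data / iscale)
             else mv$data / iscale

  # pyramid, coarsest last; drop levels that cannot resolve the menisci: a
  # level whose meniscus masks retain no interior voxel (erosion by one
  # voxel) sees the structure only through partial volume, and its energy
  # minimum misinforms the finer levels rather than guiding them
  levels <- list(list(fixed = fx, moving = mv, fmasks = fmasks, mmasks = mmasks))
  for (l in seq_len(control$levels - 1)) {
    prev <- levels[[l]]
    fm <- lapply(prev$fmasks, downsample_mask)
    mm <- lapply(prev$mmasks, downsample_mask)
    spacing_l <- 2 * prev$fixed$spacing
    resolved <- vapply(c(fm, mm), function(m)
      sum(m) >= 8 && any(erode_mask(m, spacing_l, min(spacing_l))),
      logical(1))
    if (!all(resolved)) {
      message("register_multilevel: stopping pyramid at ", l,
              " level(s); the menisci are not resolved at coarser spacing")
      break
    }
    levels[[l + 1]] <- list(
      fixed = knee_volume(downsample_array(prev$fixed$data),
                          spacing_l, prev$fixed$origin),
      moving = knee_volume(downsample_array(prev$moving$data),
                           2 * prev$moving$spacing, prev$moving$origin),
      fmasks = fm, mmasks = mm)
  }

  u <- NULL
  trace <- NULL
  for (l in rev(seq_along(levels))) {
    lv <- levels[[l]]
    d_l <- dim(lv$fixed$data)
    if (is.null(u)) {
      init <- centroid_init_field(fx, fmasks, mmasks,
                                  falloff = control$ssd_region_dilation_mm + 2)
      u <- prolongate_field(init, lv$fixed)
    } else {
      u <- prolongate_field(u, lv$fixed)
    }
    region <- dilate_mask(lv$fmasks$medial_meniscus | lv$fmasks$lateral_meniscus,
                          lv$fixed$spacing, control$ssd_region_dilation_mm)
    surface_points <- list()
    surface_dt <- list()
    for (nm in MENISCUS_NAMES) {
      surf <- mask_surface(lv$fmasks[[nm]])
      surface_points[[nm]] <- mask_world_coords(surf, lv$fixed$spacing,
                                                lv$fixed$origin)
      surface_dt[[nm]] <- contour_distance_map(lv$mmasks[[nm]],
                                               lv$fixed$spacing,
                                               lv$fixed$origin)
    }
    u <- gauss_newton_solve(u, lv$fixed, lv$moving, region, surface_points,
                            surface_dt, control, pre_transform = pre_transform)
    tr <- attr(u, "trace")
    tr$level <- l
    trace <- rbind(trace, tr)
  }

  # embed the box solution in the full grid
  full <- array(0, c(full_dim, 3))
  full[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3], ] <-
    u$vectors
  out <- deformation_field(full, fixed$spacing, fixed$origin)
  attr(out, "trace") <- trace[, c("level", "iteration", "total", "ssd",
                                  "curvature", "surface", "step_size")]
  out
}

# Moment-based warm start: each compartment starts from the translation
# between the centroids of its fixed and moving masks, blended to zero by a
# cosine falloff outside the mask. The coarsest solver level refines from
# here; a thin tube is barely resolved after two decimations, so a purely
# multilevel search can under-shoot displacements of several voxels.
centroid_init_field <- function(fixed_vol, fmasks, mmasks, falloff) {
  d <- dim(fixed_vol$data)
  sp <- fixed_vol$spacing
  u <- array(0, c(d, 3))
  w_all <- vector("list", length(MENISCUS_NAMES))
  names(w_all) <- MENISCUS_NAMES
  wsum <- array(0, d)
  for (nm in MENISCUS_NAMES) {
    fm <- fmasks[[nm]]
    dist <- surface_distance(fm, sp)
    w <- array(0, d)
    w[fm] <- 1
    ramp <- !fm & dist < falloff
    w[ramp] <- 0.5 * (1 + cos(pi * dist[ramp] / falloff))
    w[fmasks[[setdiff(MENISCUS_NAMES, nm)]]] <- 0
    w_all[[nm]] <- w
    wsum <- wsum + w
  }
  norm <- pmax(wsum, 1)
  for (nm in MENISCUS_NAMES) {
    tr <- colMeans(mask_world_coords(mmasks[[nm]], sp, fixed_vol$origin)) -
      colMeans(mask_world_coords(fmasks[[nm]], sp, fixed_vol$origin))
    w <- w_all[[nm]] / norm
    for (c_ in 1:3) u[, , , c_] <- u[, , , c_] + w * tr[c_]
  }
  deformation_field(u, sp, fixed_vol$origin)
}

# evaluate a coarse field at the voxel centres of a finer grid (trilinear,
# clamped extrapolation at the box edge); vectors are in mm so no rescaling
prolongate_field <- function(u, fine_vol) {
  d_f <- dim(fine_vol$data)
  world <- index_to_world(grid_index_matrix(d_f), fine_vol$spacing,
                          fine_vol$origin)
  idx_c <- world_to_index(world, u$spacing, u$origin)
  vec <- vapply(1:3, function(c_)
    interp3(u$vectors[, , , c_, drop = TRUE], idx_c, clamp = TRUE),
    numeric(nrow(idx_c)))
  deformation_field(array(vec, c(d_f, 3)), fine_vol$spacing, fine_vol$origin)
}
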