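# The user-facing model interface: one fitting call running the whole
# rigid + deformable + analysis chain, returning a classed object with the
# usual accessor methods.

#' Fit the meniscal motion model to an unloaded/loaded scan pair
#'
#' Runs the complete measurement chain: rigid alignment restricted to the
#' tibial bone mask, multilevel curvature-regularised deformable
#' registration of the meniscal region with the surface-distance penalty,
#' cropping of the field to the meniscal masks, PCA coordinate frame,
#' equal-arc-length partition of each meniscus, and per-compartment motion
#' averages.
#'
#' @param fixed unloaded (reference) [knee_volume].
#' @param moving loaded [knee_volume].
#' @param fixed_structures,moving_structures [structure_set]s for the two
#'   scans.
#' @param control a [registration_control].
#' @param rigid either `TRUE` (estimate the tibia-masked rigid transform),
#'   `FALSE` (scans already aligned), or a [rigid_transform] to apply.
#' @param bin_deg angular bin width (degrees) for the centerline partition.
#' @return An object of class `meniscus_motion` with components `summary`
#'   (the per-compartment motion table), `field`, `rigid`, `frame`,
#'   `partitions`, `cropped`, `trace`, and the aligned inputs.
#' @seealso [summary.meniscus_motion()], [coef.meniscus_motion()],
#'   [plot.meniscus_motion()], [predict.meniscus_motion()],
#'   [residuals.meniscus_motion()]
#' @export
fit_meniscus_motion <- function(fixed, moving, fixed_structures,
                                moving_structures,
                                control = registration_control(),
                                rigid = TRUE, bin_deg = 5) {
  cl <- match.call()
  stopifnot(inherits(fixed, "knee_volume"), inherits(moving, "knee_volume"))
  if (isTRUE(rigid)) {
    rig <- register_rigid_masked(fixed, moving,
                                 fixed_structures$masks$tibia)
  } else if (inherits(rigid, "rigid_transform")) {
    rig <- rigid
  } else {
    rig <- rigid_transform()
  }
  moving_aligned <- resample_rigid(moving, rig, fixed,
                                   background = min(moving$data))
  moving_structures_aligned <- resample_rigid(moving_structures, rig, fixed)
  field <- register_multilevel(fixed, moving_aligned, fixed_structures,
                               moving_structures_aligned, control)
  cropped <- crop_field(field, fixed_structures)
  frame <- compute_axes(fixed_structures)
  partitions <- list(
    medial = partition_meniscus(fixed_structures$masks$medial_meniscus,
                                frame, fixed$spacing, fixed$origin, bin_deg),
    lateral = partition_meniscus(fixed_structures$masks$lateral_meniscus,
                                 frame, fixed$spacing, fixed$origin, bin_deg))
  summary_tab <- summarize_motion(cropped, partitions, frame,
                                  per_voxel_norm = control$avg_per_voxel_norm)
  structure(list(call = cl, summary = summary_tab, field = field,
                 rigid = rig, frame = frame, partitions = partitions,
                 cropped = cropped, trace = attr(field, "trace"),
                 fixed = fixed, moving_aligned = moving_aligned,
                 fixed_structures = fixed_structures,
                 moving_structures_aligned = moving_structures_aligned,
                 control = control),
            class = "meniscus_motion")
}

#' @export
print.meniscus_motion <- function(x, ...) {
  cat("Meniscal motion fit\n")
  cat("  rigid: rotation (", paste(signif(x$rigid$rotation, 3), collapse = ", "),
      ") deg, translation (",
      paste(signif(x$rigid$translation, 3), collapse = ", "), ") mm\n", sep = "")
  ov <- x$summary[x$summary$scope == "Overall", ]
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  %s overall: Avg %.3f mm (ML %+.3f, AP %+.3f, SI %+.3f)\n",
                ov$meniscus[i], ov$avg_mm[i], ov$ml_mm[i], ov$ap_mm[i],
                ov$si_mm[i]))
  invisible(x)
}

#' Summary method for meniscal motion fits
#' @param object a `meniscus_motion` fit.
#' @param ... unused.
#' @return The per-compartment `motion_summary` table, with the final
#'   objective breakdown attached as attribute `"objective"`.
#' @export
summary.meniscus_motion <- function(object, ...) {
  tab <- object$summary
  tr <- object$trace
  attr(tab, "objective") <- tr[nrow(tr), c("total", "ssd", "curvature",
                                           "surface")]
  tab
}

#' @export
print.motion_summary <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Coefficients of a meniscal motion fit
#' @param object a `meniscus_motion` fit.
#' @param ... unused.
#' @return Numeric matrix (8 x 4): `avg_mm`, `ml_mm`, `ap_mm`, `si_mm` per
#'   meniscus x scope row.
#' @export
coef.meniscus_motion <- function(object, ...) {
  m <- as.matrix(object$summary[, c("avg_mm", "ml_mm", "ap_mm", "si_mm")])
  rownames(m) <- paste(object$summary$meniscus, object$summary$scope, sep = ".")
  m
}

#' Predict (warp) from a meniscal motion fit
#'
#' `"moving"` returns the rigidly aligned loaded scan warped by the fitted
#' deformation onto the unloaded anatomy; `"field"` returns the fitted
#' [deformation_field].
#'
#' @param object a `meniscus_motion` fit.
#' @param what `"moving"` or `"field"`.
#' @param ... unused.
#' @export
predict.meniscus_motion <- function(object, what = c("moving", "field"), ...) {
  what <- match.arg(what)
  if (what == "field") return(object$field)
  warp_image(object$moving_aligned, object$field,
             background = min(object$moving_aligned$data))
}

#' Intensity residuals of a meniscal motion fit
#'
#' Difference between the warped, aligned loaded scan and the unloaded scan
#' over the meniscal SSD region (NA elsewhere).
#'
#' @param object a `meniscus_motion` fit.
#' @param ... unused.
#' @return A 3D array of intensity residuals.
#' @export
residuals.meniscus_motion <- function(object, ...) {
  warped <- predict(object, "moving")
  res <- warped$data - object$fixed$data
  region <- dilate_mask(object$fixed_structures$masks$medial_meniscus |
                          object$fixed_structures$masks$lateral_meniscus,
                        object$fixed$spacing,
                        object$control$ssd_region_dilation_mm)
  res[!region] <- NA_real_
  res
}

#' Plot the objective trace of a meniscal motion fit
#'
#' Accepted total energy per Gauss-Newton iteration, one line per pyramid
#' level (log scale).
#'
#' @param x a `meniscus_motion` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.meniscus_motion <- function(x, ...) {
  tr <- x$trace
  lev <- sort(unique(tr$level), decreasing = TRUE)
  cols <- grDevices::hcl.colors(max(length(lev), 2), "Dark 3")
  graphics::plot(NA, xlim = range(tr$iteration), ylim = range(tr$total),
                 log = "y", xlab = "Gauss-Newton iteration",
                 ylab = "objective (accepted)", ...)
  for (i in seq_along(lev)) {
    s <- tr[tr$level == lev[i], ]
    graphics::lines(s$iteration, s$total, col = cols[i], lwd = 2)
    graphics::points(s$iteration, s$total, col = cols[i], pch = 16, cex = 0.6)
  }
  graphics::legend("topright", legend = paste("level", lev), col =
                     cols[seq_along(lev)], lwd = 2, bty = "n")
  invisible(x)
}
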