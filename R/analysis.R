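# From dense field to compartment motion: crop displacement vectors to the
# meniscal masks, build the tibia-based anatomical frame by PCA of the
# unloaded meniscal voxels, split each meniscus into anterior horn /
# intermediate part / posterior horn by equal centerline arc length, and
# average the motion per compartment with ML/AP projections.

#' Crop a deformation field to the meniscal masks
#'
#' Retains displacement vectors exactly on the medial and lateral meniscus
#' voxels of the unloaded scan; everything else is discarded from the
#' analysis.
#'
#' @param field a [deformation_field].
#' @param structures a [structure_set] on the same grid.
#' @return An object of class `cropped_field`: a list with `vectors`
#'   (n x 3, mm), `world` (n x 3 voxel centres, mm), `meniscus` (factor,
#'   `"medial"`/`"lateral"`), `lin` (linear voxel indices) and grid metadata.
#' @export
crop_field <- function(field, structures) {
  stopifnot(inherits(field, "deformation_field"),
            inherits(structures, "structure_set"))
  if (!same_grid(field, structures))
    stop_grid_mismatch(field, structures, "field and structures")
  out <- list()
  vecs <- matrix(field$vectors, ncol = 3)
  for (nm in MENISCUS_NAMES) {
    mask <- structures$masks[[nm]]
    if (!any(mask)) stop("crop_field: empty meniscus mask ", nm, call. = FALSE)
    lin <- which(mask)
    out[[nm]] <- list(lin = lin, vectors = vecs[lin, , drop = FALSE],
                      world = mask_world_coords(mask, structures$spacing,
                                                structures$origin))
  }
  structure(list(
    vectors = rbind(out$medial_meniscus$vectors, out$lateral_meniscus$vectors),
    world = rbind(out$medial_meniscus$world, out$lateral_meniscus$world),
    lin = c(out$medial_meniscus$lin, out$lateral_meniscus$lin),
    meniscus = factor(rep(c("medial", "lateral"),
                          c(nrow(out$medial_meniscus$vectors),
                            nrow(out$lateral_meniscus$vectors))),
                      levels = c("medial", "lateral")),
    spacing = structures$spacing, origin = structures$origin,
    dim = dim(field$vectors)[1:3]), class = "cropped_field")
}

#' Anatomical coordinate frame from meniscal PCA
#'
#' Eigen-decomposition of the covariance of the pooled world coordinates of
#' all medial and lateral meniscus voxels in the unloaded position. The
#' first principal direction is the medio-lateral axis, the second the
#' anterior-posterior axis, the third completes the frame. Signs follow the
#' reporting convention: ML positive towards lateral (fixed by the
#' medial-to-lateral centroid direction), AP positive towards posterior
#' (fixed by the canonical image orientation), SI = ML x AP (right-handed).
#'
#' @param structures [structure_set] of the unloaded scan.
#' @return An object of class `coordinate_frame` with unit vectors
#'   `ml_axis`, `ap_axis`, `si_axis` and a `provenance` note.
#' @export
compute_axes <- function(structures) {
  stopifnot(inherits(structures, "structure_set"))
  pts <- rbind(mask_world_coords(structures$masks$medial_meniscus,
                                 structures$spacing, structures$origin),
               mask_world_coords(structures$masks$lateral_meniscus,
                                 structures$spacing, structures$origin))
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] <= 1e-8 * ev$values[1])
    stop("compute_axes: degenerate meniscal point cloud (rank < 3)",
         call. = FALSE)
  ml <- ev$vectors[, 1]
  ap <- ev$vectors[, 2]
  med_c <- colMeans(mask_world_coords(structures$masks$medial_meniscus,
                                      structures$spacing, structures$origin))
  lat_c <- colMeans(mask_world_coords(structures$masks$lateral_meniscus,
                                      structures$spacing, structures$origin))
  if (sum(ml * (lat_c - med_c)) < 0) ml <- -ml
  # canonical axes are RAS: +y anterior, so posterior is -y
  if (sum(ap * c(0, -1, 0)) < 0) ap <- -ap
  si <- c(ml[2] * ap[3] - ml[3] * ap[2],
          ml[3] * ap[1] - ml[1] * ap[3],
          ml[1] * ap[2] - ml[2] * ap[1])
  structure(list(ml_axis = ml / sqrt(sum(ml^2)),
                 ap_axis = ap / sqrt(sum(ap^2)),
                 si_axis = si / sqrt(sum(si^2)),
                 provenance = "PCA of pooled medial+lateral meniscal voxels, unloaded scan"),
            class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat("<coordinate_frame>\n")
  for (nm in c("ml_axis", "ap_axis", "si_axis"))
    cat(" ", format(nm, width = 8), paste(signif(x[[nm]], 4), collapse = ", "),
        "\n")
  cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Partition a meniscus into AH / IP / PH by equal centerline arc length
#'
#' Projects the meniscal voxels onto the ML-AP plane, orders them by polar
#' angle about the projected centroid (angular bins of `bin_deg`, per-bin 3D
#' centroids forming the centerline polyline), cuts the cumulative arc
#' length at 1/3 and 2/3, and assigns each voxel the segment of its nearest
#' centerline vertex (in-plane Euclidean distance; ties resolved towards the
#' lower arc length). The segment whose centerline end lies most anterior is
#' the anterior horn.
#'
#' @param mask non-empty single-component logical 3D array (one meniscus).
#' @param frame a [coordinate_frame].
#' @param spacing,origin grid metadata of the mask.
#' @param bin_deg angular bin width (degrees) of the centerline extraction.
#' @return An object of class `meniscus_partition`: `labels` (factor
#'   `AH`/`IP`/`PH` per mask voxel, in `which(mask)` order), `lin` (linear
#'   voxel indices), `centerline` (k x 3 polyline, mm), `arclength`
#'   (cumulative, mm), `cut_arclengths` (the two cuts, mm), `segment`
#'   (segment of each centerline vertex).
#' @export
partition_meniscus <- function(mask, frame, spacing, origin = c(0, 0, 0),
                               bin_deg = 5) {
  if (!any(mask)) stop("partition_meniscus: empty mask", call. = FALSE)
  comp <- connected_components(mask)
  if (max(comp) > 1L)
    stop("partition_meniscus: mask has ", max(comp),
         " connected components; expected a single C-shaped body", call. = FALSE)
  pts <- mask_world_coords(mask, spacing, origin)
  ctr <- colMeans(pts)
  a <- as.numeric((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% frame$ml_axis)
  b <- as.numeric((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% frame$ap_axis)
  theta <- atan2(b, a)

  # C-shape validation: about the least-squares (Kasa) circle centre of the
  # projected voxels, the occupied angular span must reach at least 90 deg
  # (about the centroid even a short arc stub spans a wide angle)
  kasa <- tryCatch({
    A <- cbind(a, b, 1)
    sol <- solve(crossprod(A), crossprod(A, -(a^2 + b^2)))
    c(-sol[1] / 2, -sol[2] / 2)
  }, error = function(e) c(0, 0))
  th_k <- atan2(b - kasa[2], a - kasa[1])
  rad_k <- sqrt((a - kasa[1])^2 + (b - kasa[2])^2)
  bin <- 2 * pi * bin_deg / 360
  nbins <- round(360 / bin_deg)
  occ_k <- sort(unique(floor(((th_k + pi) %% (2 * pi)) / bin) %% nbins))
  gaps_k <- diff(c(occ_k, occ_k[1] + nbins))
  span_k <- (nbins - max(gaps_k) + 1) * bin_deg
  half_spread <- diff(range(rad_k)) / 2
  if (span_k < 90 || half_spread > 0.4 * mean(rad_k))
    stop("partition_meniscus: angular span ", round(span_k, 1),
         " deg < 90 deg about the fitted arc centre (or radial spread ",
         round(half_spread, 1), " mm too large for arc radius ",
         round(mean(rad_k), 1), " mm); mask is not C-shaped", call. = FALSE)

  # unwrap across the C opening: cut at the largest unoccupied angular gap
  occ <- sort(unique(floor(((theta + pi) %% (2 * pi)) / bin) %% nbins))
  gaps <- diff(c(occ, occ[1] + nbins))
  cut_bin <- occ[which.max(gaps)]
  theta_shift <- (theta + pi - (cut_bin + 1) * bin) %% (2 * pi)

  bins <- floor(theta_shift / bin)
  ub <- sort(unique(bins))
  cl <- t(vapply(ub, function(bb) colMeans(pts[bins == bb, , drop = FALSE]),
                 numeric(3)))
  # one [1,2,1]/4 pass along the polyline: bin boundaries cut the tube
  # obliquely where the centroid is off the arc centre, and the resulting
  # radial zigzag of raw bin centroids inflates the measured arc length
  nv <- nrow(cl)
  if (nv >= 3)
    cl[2:(nv - 1), ] <- (cl[1:(nv - 2), ] + 2 * cl[2:(nv - 1), ] +
                           cl[3:nv, ]) / 4
  seglen <- sqrt(rowSums((cl[-1, , drop = FALSE] -
                            cl[-nrow(cl), , drop = FALSE])^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  cuts <- total * c(1, 2) / 3
  segment <- 1L + (arc >= cuts[1]) + (arc >= cuts[2])

  # nearest centerline vertex, in the ML-AP plane
  cl_a <- as.numeric((cl - matrix(ctr, nrow(cl), 3, byrow = TRUE)) %*% frame$ml_axis)
  cl_b <- as.numeric((cl - matrix(ctr, nrow(cl), 3, byrow = TRUE)) %*% frame$ap_axis)
  d2 <- outer(a, cl_a, `-`)^2 + outer(b, cl_b, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  vox_seg <- segment[nearest]

  # anterior horn = segment at the most anterior centerline end (+AP = posterior)
  end_b <- c(cl_b[1], cl_b[length(cl_b)])
  lab3 <- if (end_b[1] <= end_b[2]) c("AH", "IP", "PH") else c("PH", "IP", "AH")
  labels <- factor(lab3[vox_seg], levels = c("AH", "IP", "PH"))
  structure(list(labels = labels, lin = which(mask), centerline = cl,
                 arclength = arc, cut_arclengths = cuts,
                 segment = factor(lab3[segment], levels = c("AH", "IP", "PH")),
                 bin_deg = bin_deg),
            class = "meniscus_partition")
}

#' @export
print.meniscus_partition <- function(x, ...) {
  cat("<meniscus_partition> ", length(x$lin), " voxels, centerline ",
      nrow(x$centerline), " vertices, arc length ",
      signif(max(x$arclength), 4), " mm\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Summarise meniscal motion per compartment
#'
#' For each meniscus and each scope (Overall and the three arc-length
#' compartments) the mean 3D displacement vector of the scope's voxels is
#' projected on the anatomical axes: `ml_mm` (+ = lateral), `ap_mm`
#' (+ = posterior), `si_mm` (+ = superior); `avg_mm` is the Euclidean norm
#' of the mean vector (or the mean of per-voxel norms when
#' `per_voxel_norm = TRUE`).
#'
#' @param cropped a [crop_field()] result.
#' @param partitions named list with entries `medial` and `lateral`, each a
#'   [partition_meniscus()] result on the corresponding mask.
#' @param frame a [coordinate_frame].
#' @param per_voxel_norm report Avg as the mean of per-voxel displacement
#'   norms instead of the norm of the mean vector.
#' @return A `motion_summary` data frame with columns `meniscus`
#'   (`MM`/`LM`), `scope` (`Overall`/`AH`/`IP`/`PH`), `avg_mm`, `ml_mm`,
#'   `ap_mm`, `si_mm`, `n_voxels`.
#' @export
summarize_motion <- function(cropped, partitions, frame,
                             per_voxel_norm = FALSE) {
  stopifnot(inherits(cropped, "cropped_field"),
            inherits(frame, "coordinate_frame"))
  rows <- list()
  for (men in c("medial", "lateral")) {
    sel <- cropped$meniscus == men
    vec <- cropped$vectors[sel, , drop = FALSE]
    lin <- cropped$lin[sel]
    part <- partitions[[men]]
    if (is.null(part)) stop("summarize_motion: missing partition for ", men,
                            call. = FALSE)
    labs <- part$labels[match(lin, part$lin)]
    if (anyNA(labs))
      stop("summarize_motion: partition does not cover the cropped field for ",
           men, call. = FALSE)
    men_code <- if (men == "medial") "MM" else "LM"
    for (scope in c("Overall", "AH", "IP", "PH")) {
      take <- if (scope == "Overall") rep(TRUE, nrow(vec)) else labs == scope
      if (!any(take)) {
        rows[[length(rows) + 1]] <- data.frame(
          meniscus = men_code, scope = scope, avg_mm = NA_real_,
          ml_mm = NA_real_, ap_mm = NA_real_, si_mm = NA_real_, n_voxels = 0L)
        next
      }
      v <- vec[take, , drop = FALSE]
      mv <- colMeans(v)
      avg <- if (per_voxel_norm) mean(sqrt(rowSums(v^2))) else sqrt(sum(mv^2))
      rows[[length(rows) + 1]] <- data.frame(
        meniscus = men_code, scope = scope, avg_mm = avg,
        ml_mm = sum(mv * frame$ml_axis), ap_mm = sum(mv * frame$ap_axis),
        si_mm = sum(mv * frame$si_axis), n_voxels = sum(take))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("motion_summary", "data.frame")
  out
}

#' Write (and read back) a per-case motion summary
#'
#' CSV with one row per meniscus x scope.
#'
#' @param summary a `motion_summary` data frame.
#' @param path output CSV path.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "data.frame"))
  write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("motion_summary", "data.frame")
  out
}

#' Aggregate per-case summaries into cohort mean and SD
#'
#' Across-case descriptive statistics per meniscus x scope cell, matching
#' the mean (SD) layout used to report cohort motion tables.
#'
#' @param summaries list of `motion_summary` data frames (or CSV paths).
#' @return Data frame with columns `meniscus`, `scope`, and mean/sd of
#'   `avg_mm`, `ml_mm`, `ap_mm`, `si_mm`, plus `n_cases`. SD columns are NA
#'   with a single case.
#' @export
aggregate_cohort <- function(summaries) {
  summaries <- lapply(summaries, function(s)
    if (is.character(s)) read_summary(s) else s)
  all <- do.call(rbind, summaries)
  cells <- unique(all[, c("meniscus", "scope")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- all$meniscus == cells$meniscus[i] & all$scope == cells$scope[i]
    sub <- all[sel, ]
    out <- data.frame(meniscus = cells$meniscus[i], scope = cells$scope[i],
                      n_cases = nrow(sub))
    for (col in c("avg_mm", "ml_mm", "ap_mm", "si_mm")) {
      out[[paste0(col, "_mean")]] <- mean(sub[[col]])
      out[[paste0(col, "_sd")]] <- if (nrow(sub) > 1) sd(sub[[col]]) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
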