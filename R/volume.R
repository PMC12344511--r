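#' @useDynLib menisci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils write.csv read.csv modifyList
NULL

STRUCTURE_NAMES <- c("femur", "tibia", "femoral_cartilage", "tibial_cartilage",
                     "medial_meniscus", "lateral_meniscus")
MENISCUS_NAMES <- c("medial_meniscus", "lateral_meniscus")

#' 3D image volume on a regular grid
#'
#' A scalar intensity grid with physical voxel spacing and world origin.
#' Internally all data are held in a canonical RAS-style axis order
#' (+x right/lateral for a right knee, +y anterior, +z superior), so the
#' world position of 0-based voxel index `(i, j, k)` is
#' `origin + c(i, j, k) * spacing`.
#'
#' @param data numeric 3D array of intensities (finite).
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @param orientation three-letter axis code recording the canonical
#'   orientation of the stored axes (always "RAS" internally).
#' @return An object of class `knee_volume`.
#' @export
knee_volume <- function(data, spacing, origin = c(0, 0, 0), orientation = "RAS") {
  if (length(dim(data)) != 3L)
    stop("knee_volume: `data` must be a 3D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("knee_volume: spacing must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("knee_volume: origin must be 3 finite values", call. = FALSE)
  if (any(!is.finite(data)))
    stop("knee_volume: intensities must all be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "knee_volume")
}

#' @export
print.knee_volume <- function(x, ...) {
  cat("<knee_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "),
      ") mm [", x$orientation, "]\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

grid_meta <- function(x) {
  a <- if (inherits(x, "knee_volume")) x$data
  else if (inherits(x, "deformation_field")) x$vectors
  else if (inherits(x, "structure_set")) x$masks[[1]]
  else if (inherits(x, "distance_map")) x$values
  else if (is.array(x)) x
  else stop("grid_meta: unsupported object", call. = FALSE)
  list(dim = dim(a),
       spacing = if (is.list(x)) x$spacing else NULL,
       origin = if (is.list(x)) x$origin else NULL)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_meta(a); gb <- grid_meta(b)
  identical(ga$dim[1:3], gb$dim[1:3]) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stop_grid_mismatch <- function(a, b, what = "inputs") {
  ga <- grid_meta(a); gb <- grid_meta(b)
  stop("grid mismatch between ", what, ": shape ",
       paste(ga$dim[1:3], collapse = "x"), " vs ", paste(gb$dim[1:3], collapse = "x"),
       ", spacing (", paste(signif(ga$spacing, 6), collapse = ", "), ") vs (",
       paste(signif(gb$spacing, 6), collapse = ", "), ")", call. = FALSE)
}

#' Dense displacement field on a reference grid
#'
#' Per-voxel 3D displacements in millimetres along the canonical world axes.
#' The displacement `u(x)` maps the reference-grid world position `x` to the
#' corresponding position `x + u(x)` in the moving image.
#'
#' @param vectors numeric 4D array `dim x 3` of displacements (mm).
#' @param spacing,origin grid metadata of the reference volume.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(vectors, spacing, origin = c(0, 0, 0)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("deformation_field: `vectors` must be a 4D array with last dimension 3",
         call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("deformation_field: all components must be finite", call. = FALSE)
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat("<deformation_field> ", paste(dim(x$vectors)[1:3], collapse = " x "),
      " voxels, |u| max ", signif(max(mag), 4), " mm, mean ",
      signif(mean(mag), 4), " mm\n", sep = "")
  invisible(x)
}

#' Per-structure binary masks sharing one grid
#'
#' Holds one binary mask per knee structure (femur, tibia, femoral and tibial
#' cartilage, medial and lateral meniscus) on the grid of a companion volume.
#'
#' @param masks named list of logical 3D arrays; names must be a subset of the
#'   six canonical structures and must include both menisci.
#' @param spacing,origin grid metadata shared with the companion volume.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0)) {
  if (!all(names(masks) %in% STRUCTURE_NAMES))
    stop("structure_set: unknown structure name(s): ",
         paste(setdiff(names(masks), STRUCTURE_NAMES), collapse = ", "),
         call. = FALSE)
  if (!all(MENISCUS_NAMES %in% names(masks)))
    stop("structure_set: both meniscus masks are required", call. = FALSE)
  d <- NULL
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (length(dim(m)) != 3L)
      stop("structure_set: mask '", nm, "' is not 3D", call. = FALSE)
    masks[[nm]] <- array(as.logical(m), dim(m))
    if (is.null(d)) d <- dim(m)
    else if (!identical(dim(m), d))
      stop("grid mismatch between structure masks: '", nm, "' has shape ",
           paste(dim(m), collapse = "x"), " vs ", paste(d, collapse = "x"),
           call. = FALSE)
  }
  for (nm in MENISCUS_NAMES)
    if (!any(masks[[nm]]))
      stop("structure_set: meniscus mask '", nm, "' is empty", call. = FALSE)
  if (any(masks$medial_meniscus & masks$lateral_meniscus))
    stop("structure_set: medial and lateral meniscus masks overlap", call. = FALSE)
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cnt <- vapply(x$masks, sum, numeric(1))
  cat("<structure_set> ", paste(dim(x$masks[[1]]), collapse = " x "), " voxels\n",
      sep = "")
  for (nm in names(cnt)) cat("  ", format(nm, width = 18), cnt[[nm]], "voxels\n")
  invisible(x)
}

#' World coordinates of mask voxels
#'
#' @param mask logical 3D array.
#' @param spacing,origin grid metadata.
#' @return n x 3 matrix of world positions (mm) of the TRUE voxels.
#' @export
mask_world_coords <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}
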