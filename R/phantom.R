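# Synthetic knee phantom: two bone-like bodies, thin cartilage layers and two
# C-shaped meniscal tubes, imaged twice with a small whole-leg rigid
# repositioning and a smooth per-compartment meniscal displacement between
# the scans. The loaded scan is synthesised by backward warping of the
# reference, so the generated truth field is exactly the field an ideal
# registration should recover after rigid alignment.

#' Phantom specification
#'
#' Defines the geometry, contrast, motion and noise of a synthetic knee case.
#' Meniscal motions are given in anatomical components (ML, AP, SI; + =
#' lateral / posterior / superior), so the same specification describes left
#' and right knees consistently.
#'
#' @param grid_shape integer length-3 grid size (voxels).
#' @param spacing voxel size in mm.
#' @param side `"right"` or `"left"`; controls which world x direction is
#'   lateral (+x for a right knee).
#' @param meniscus_arc_radius radius of the meniscal centerline arc (mm).
#' @param meniscus_tube_radius tube (cross-section) radius (mm).
#' @param meniscus_arc_span angular extent of the C-shape, degrees, in
#'   (90, 330).
#' @param compartment_offset distance of each arc centre from the joint
#'   midline (mm).
#' @param rigid_offset whole-leg repositioning between scans: rotation
#'   degrees about x/y/z then translation mm, each component within ±10.
#' @param meniscal_motion list with `medial` and `lateral` length-3 vectors:
#'   mean meniscal displacement in mm along (ML, AP, SI); magnitude ≤ 3 mm.
#' @param perturbation_amplitude amplitude (mm, vector norm bound) of a
#'   smooth low-frequency sinusoidal perturbation added to the constant
#'   motion.
#' @param falloff_mm distance over which meniscal motion blends to zero
#'   outside the meniscus (cosine falloff).
#' @param noise_sd Gaussian intensity noise standard deviation, added
#'   independently to each scan.
#' @param intensities named list of mean tissue intensities.
#' @param meniscus_texture relative amplitude of a smooth along-arc intensity
#'   modulation inside each meniscus (two cycles over the full circle),
#'   emulating the horn-to-body signal variation of real menisci; perfectly
#'   homogeneous menisci (0) leave motion along the tube tangent
#'   unobservable for any intensity-based registration.
#' @param seed integer seed; all randomness is a pure function of it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing = c(0.6, 0.6, 0.6),
                         side = c("right", "left"),
                         meniscus_arc_radius = 9,
                         meniscus_tube_radius = 1.5,
                         meniscus_arc_span = 250,
                         compartment_offset = 10.5,
                         rigid_offset = c(2, -1.5, 1, 2, -1, 1.5),
                         meniscal_motion = list(medial = c(1.1, 0.6, 0.1),
                                                lateral = c(0.55, -1.3, 0.1)),
                         perturbation_amplitude = 0.2,
                         falloff_mm = 5,
                         noise_sd = 5,
                         intensities = list(background = 20, bone = 140,
                                            cartilage = 90, meniscus = 220),
                         meniscus_texture = 0.15,
                         seed = 1) {
  side <- match.arg(side)
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               side = side,
               meniscus_arc_radius = meniscus_arc_radius,
               meniscus_tube_radius = meniscus_tube_radius,
               meniscus_arc_span = meniscus_arc_span,
               compartment_offset = compartment_offset,
               rigid_offset = as.numeric(rigid_offset),
               meniscal_motion = lapply(meniscal_motion, as.numeric),
               perturbation_amplitude = perturbation_amplitude,
               falloff_mm = falloff_mm,
               noise_sd = noise_sd, intensities = intensities,
               meniscus_texture = meniscus_texture,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$meniscus_tube_radius >= s$meniscus_arc_radius)
    stop("phantom_spec: tube radius must be smaller than arc radius", call. = FALSE)
  if (s$meniscus_arc_span <= 90 || s$meniscus_arc_span >= 330)
    stop("phantom_spec: arc span must lie in (90, 330) degrees", call. = FALSE)
  if (any(abs(s$rigid_offset[1:3]) > 10) || any(abs(s$rigid_offset[4:6]) > 10))
    stop("phantom_spec: rigid offset limited to 10 degrees / 10 mm per component",
         call. = FALSE)
  for (nm in c("medial", "lateral")) {
    v <- s$meniscal_motion[[nm]]
    if (length(v) != 3L || sqrt(sum(v^2)) > 3)
      stop("phantom_spec: ", nm, " meniscal displacement must be a 3-vector of ",
           "magnitude <= 3 mm", call. = FALSE)
  }
  if (s$perturbation_amplitude < 0 || s$perturbation_amplitude > 0.5)
    stop("phantom_spec: perturbation amplitude must be in [0, 0.5] mm", call. = FALSE)
  vmax <- max(vapply(s$meniscal_motion, function(v) sqrt(sum(v^2)), numeric(1))) +
    s$perturbation_amplitude
  if (vmax > 0 && s$falloff_mm < 1.6 * vmax)
    stop("phantom_spec: falloff_mm must be at least 1.6x the largest ",
         "displacement magnitude so the ground-truth motion stays invertible",
         call. = FALSE)
  # the moving-scan menisci must stay inside the field of view
  half_fov <- (s$grid_shape[1:2] - 1) * s$spacing[1:2] / 2
  reach <- s$compartment_offset + s$meniscus_arc_radius +
    s$meniscus_tube_radius + max(abs(s$rigid_offset[4:5])) +
    s$compartment_offset * sin(max(abs(s$rigid_offset[1:3])) * pi / 180) + vmax
  if (reach > min(half_fov))
    stop("phantom_spec: meniscal geometry plus rigid offset and motion (",
         round(reach, 1), " mm) exceeds the in-plane half field of view (",
         round(min(half_fov), 1), " mm); enlarge the grid or shrink the ",
         "geometry", call. = FALSE)
  invisible(s)
}

# world coordinate arrays (mm) of every voxel along each axis
phantom_coords <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing
  list(x = (seq_len(d[1]) - 1) * sp[1],
       y = (seq_len(d[2]) - 1) * sp[2],
       z = (seq_len(d[3]) - 1) * sp[3],
       centre = (d - 1) * sp / 2)
}

# anatomical (ML, AP, SI) -> world (x, y, z); +x lateral for a right knee,
# +y anterior in RAS so +AP(posterior) maps to -y.
anat_to_world <- function(v, side) {
  c(if (side == "right") v[1] else -v[1], -v[2], v[3])
}

meniscus_mask_one <- function(spec, which) {
  co <- phantom_coords(spec)
  lat_sign <- if (spec$side == "right") 1 else -1
  s <- if (which == "medial") -lat_sign else lat_sign   # side of the midline
  mx <- co$centre[1] + s * spec$compartment_offset
  zc <- co$centre[3] + 0.5
  d <- spec$grid_shape
  dx <- co$x - mx
  dy <- co$y - co$centre[2]
  DX <- array(rep(dx, times = d[2] * d[3]), d)
  DY <- array(rep(rep(dy, each = d[1]), times = d[3]), d)
  DZ <- array(rep(co$z - zc, each = d[1] * d[2]), d)
  rho <- sqrt(DX^2 + DY^2)
  torus <- (rho - spec$meniscus_arc_radius)^2 + DZ^2 <= spec$meniscus_tube_radius^2
  # C opening faces the joint midline (direction -s along x)
  gap_half <- (360 - spec$meniscus_arc_span) / 2 * pi / 180
  cosang <- ifelse(rho > 0, (-s) * DX / pmax(rho, 1e-12), 1)
  torus & (acos(pmin(pmax(cosang, -1), 1)) >= gap_half)
}

#' Build the phantom anatomy (one scan)
#'
#' Constructs the reference (unloaded) intensity volume and its six structure
#' masks: a flat-topped tibial slab, two femoral condylar half-ellipsoids,
#' thin cartilage layers and two mirrored C-shaped meniscal tubes. Tissue
#' means come from `spec$intensities`; Gaussian noise of sd `spec$noise_sd`
#' is added under the spec seed.
#'
#' @param spec a [phantom_spec].
#' @param noise add intensity noise (set `FALSE` for the clean render).
#' @return List with elements `volume` ([knee_volume]) and `structures`
#'   ([structure_set]).
#' @export
build_anatomy <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec)
  d <- spec$grid_shape
  DX <- array(rep(co$x - co$centre[1], times = d[2] * d[3]), d)
  DY <- array(rep(rep(co$y - co$centre[2], each = d[1]), times = d[3]), d)
  Z <- array(rep(co$z, each = d[1] * d[2]), d)
  zc <- co$centre[3]
  extent <- (d - 1) * spec$spacing
  # elliptical shaft with an anterior tuberosity-like bump: the cross-section
  # must not be rotationally symmetric or the tibia-masked rigid rotation
  # about the shaft axis would be unidentifiable
  ax_t <- 0.42 * extent[1]
  by_t <- 0.34 * extent[2]
  ell_t <- (DX / ax_t)^2 + (DY / by_t)^2 <= 1
  bump <- DX^2 + (DY - by_t)^2 <= (0.12 * extent[2])^2
  foot_t <- ell_t | bump
  tibia <- foot_t & Z >= 2 & Z <= zc - 2.5
  tibial_cartilage <- foot_t & Z > zc - 2.5 & Z <= zc - 1.3

  lat_sign <- if (spec$side == "right") 1 else -1
  cond <- function(s) {
    cx <- s * spec$compartment_offset
    ((DX - cx) / 12)^2 + (DY / 16)^2 + ((Z - (zc + 12)) / 10)^2 <= 1
  }
  ell <- cond(lat_sign) | cond(-lat_sign)
  femur <- ell & Z >= zc + 3.4
  femoral_cartilage <- ell & Z >= zc + 2.2 & Z < zc + 3.4

  medial <- meniscus_mask_one(spec, "medial")
  lateral <- meniscus_mask_one(spec, "lateral")

  masks <- list(femur = femur, tibia = tibia,
                femoral_cartilage = femoral_cartilage,
                tibial_cartilage = tibial_cartilage,
                medial_meniscus = medial, lateral_meniscus = lateral)
  total <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), d)))
  if (any(total > 1L))
    stop("build_anatomy: structures overlap for this specification (",
         sum(total > 1L), " voxels); geometry infeasible", call. = FALSE)

  ints <- spec$intensities
  img <- array(ints$background, d)
  img[femur | tibia] <- ints$bone
  img[femoral_cartilage | tibial_cartilage] <- ints$cartilage
  img[medial | lateral] <- ints$meniscus
  if (spec$meniscus_texture > 0) {
    # smooth along-arc signal modulation (horn/body contrast); without any
    # internal structure the tangential motion component is unobservable.
    # The arc angle is measured from each meniscus's own opening direction,
    # so medial and lateral carry the same anatomy-relative pattern.
    for (pair in list(list(mask = medial, s = -lat_sign),
                      list(mask = lateral, s = lat_sign))) {
      idx <- which(pair$mask)
      phi <- atan2(DY[idx],
                   -pair$s * (DX[idx] - pair$s * spec$compartment_offset))
      img[idx] <- ints$meniscus *
        (1 + spec$meniscus_texture * cos(2 * phi + 0.7))
    }
  }
  # two binomial passes emulate the acquisition point-spread function
  # (effective resolution slightly above the voxel size): real MR tissue
  # boundaries are never single-voxel intensity steps
  img <- smooth3(smooth3(img))
  if (noise && spec$noise_sd > 0)
    img <- img + with_seed(spec$seed,
                           array(rnorm(prod(d), 0, spec$noise_sd), d))
  list(volume = knee_volume(img, spec$spacing),
       structures = structure_set(masks, spec$spacing))
}

#' Ground-truth meniscal displacement field
#'
#' Each meniscus moves by its constant specified vector, blended to zero by a
#' cosine falloff over `falloff_mm` outside the mask, plus a low-frequency
#' sinusoidal perturbation of the stated amplitude. Inside each meniscus mask
#' (hence inside any erosion of it) the constant part is exact.
#'
#' @param spec a [phantom_spec].
#' @param structures the [structure_set] from [build_anatomy()].
#' @return A [deformation_field] on the reference grid, in mm.
#' @export
make_truth_field <- function(spec, structures) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(structures, "structure_set"))
  d <- spec$grid_shape
  n <- prod(d)
  u <- array(0, c(d, 3))
  wsum <- array(0, d)
  parts <- list(medial = structures$masks$medial_meniscus,
                lateral = structures$masks$lateral_meniscus)
  w <- list()
  for (nm in names(parts)) {
    mask <- parts[[nm]]
    dist <- surface_distance(mask, spec$spacing)
    wi <- array(0, d)
    wi[mask] <- 1
    ramp <- !mask & dist < spec$falloff_mm
    wi[ramp] <- 0.5 * (1 + cos(pi * dist[ramp] / spec$falloff_mm))
    wi[parts[[setdiff(names(parts), nm)]]] <- 0  # exclusive compartments
    w[[nm]] <- wi
    wsum <- wsum + wi
  }
  norm <- pmax(wsum, 1)
  pert <- truth_perturbation(spec)
  for (nm in names(parts)) {
    v <- anat_to_world(spec$meniscal_motion[[nm]], spec$side)
    wi <- w[[nm]] / norm
    for (c_ in 1:3)
      u[, , , c_] <- u[, , , c_] + wi * (v[c_] + pert[[c_]])
  }
  deformation_field(u, spec$spacing)
}

# smooth sinusoidal perturbation, per-component amplitude amp/sqrt(3) so the
# vector norm never exceeds amp; wavelength ~30 mm, phases/directions seeded
truth_perturbation <- function(spec) {
  d <- spec$grid_shape
  amp <- spec$perturbation_amplitude / sqrt(3)
  if (spec$perturbation_amplitude == 0)
    return(list(array(0, d), array(0, d), array(0, d)))
  pars <- with_seed(spec$seed + 1000L, {
    list(dirs = matrix(rnorm(9), 3, 3), phases = runif(3, 0, 2 * pi))
  })
  co <- phantom_coords(spec)
  X <- array(rep(co$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(co$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(co$z, each = d[1] * d[2]), d)
  lambda <- 30
  out <- vector("list", 3)
  for (c_ in 1:3) {
    k <- pars$dirs[, c_] / sqrt(sum(pars$dirs[, c_]^2))
    out[[c_]] <- amp * sin(2 * pi * (X * k[1] + Y * k[2] + Z * k[3]) / lambda +
                             pars$phases[c_])
  }
  out
}

#' Warp an image by a displacement field
#'
#' Backward warping: the output at grid position `x` is the input sampled by
#' trilinear interpolation at `x + u(x)`. Samples outside the grid take the
#' `background` value.
#'
#' @param image a [knee_volume].
#' @param field a [deformation_field] on the image grid.
#' @param background intensity for out-of-grid samples.
#' @param nearest use nearest-neighbour sampling (for masks).
#' @return A [knee_volume] on the same grid.
#' @export
warp_image <- function(image, field, background = 0, nearest = FALSE) {
  stopifnot(inherits(image, "knee_volume"), inherits(field, "deformation_field"))
  if (!same_grid(image, field)) stop_grid_mismatch(image, field, "image and field")
  d <- dim(image$data)
  idx <- grid_index_matrix(d)
  uvox <- sweep(matrix(field$vectors, ncol = 3), 2, field$spacing, `/`)
  out <- interp3(image$data, idx + uvox, background = background, nearest = nearest)
  knee_volume(array(out, d), image$spacing, image$origin)
}

#' Generate a phantom case (unloaded + loaded scan pair)
#'
#' Renders the clean anatomy, applies the whole-leg rigid offset and the
#' meniscal truth field to synthesise the loaded scan and its masks by
#' backward warping, then adds independent noise to both scans. The stored
#' `truth_field` is the meniscal displacement expressed on the reference grid
#' after rigid alignment, i.e. exactly what the deformable stage should
#' recover; `truth_rigid` maps reference (fixed) world coordinates to
#' moving-scan coordinates.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_case` with elements `reference`,
#'   `moving` (each a list of `volume` and `structures`), `truth_field`,
#'   `truth_rigid` and `spec`.
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  anat <- build_anatomy(spec, noise = FALSE)
  truth <- make_truth_field(spec, anat$structures)
  co <- phantom_coords(spec)
  rig <- rigid_transform(rotation = spec$rigid_offset[1:3],
                         translation = spec$rigid_offset[4:6],
                         center = co$centre)
  d <- spec$grid_shape
  idx <- grid_index_matrix(d)
  world <- index_to_world(idx, spec$spacing, c(0, 0, 0))
  # material preimage of each moving-grid point: undo the rigid move, then
  # the meniscal displacement (u is constant where it is nonzero-critical,
  # so evaluating it at the rigidly-unmoved point is exact there)
  pre <- transform_points(rigid_inverse(rig), world)
  # material point x of each moving-grid position: invert the forward map
  # x + u(x) by fixed-point iteration (u is smooth with |grad u| < 1 by the
  # falloff bound), so moving(x + u(x)) = fixed(x) holds exactly and the
  # stored truth field is precisely the field registration should recover
  pre_idx <- world_to_index(pre, spec$spacing, c(0, 0, 0))
  ux <- array(truth$vectors[, , , 1], d)
  uy <- array(truth$vectors[, , , 2], d)
  uz <- array(truth$vectors[, , , 3], d)
  x_idx <- pre_idx
  for (it in 1:12) {
    u_at <- cbind(interp3(ux, x_idx, clamp = TRUE),
                  interp3(uy, x_idx, clamp = TRUE),
                  interp3(uz, x_idx, clamp = TRUE))
    x_new <- pre_idx - sweep(u_at, 2, spec$spacing, `/`)
    shift <- max(abs(x_new - x_idx))
    x_idx <- x_new
    if (shift < 1e-4) break
  }
  src_idx <- x_idx
  bg <- spec$intensities$background
  mov_img <- array(interp3(anat$volume$data, src_idx, background = bg), d)
  # masks resampled as linear-interpolated indicators thresholded at 0.5:
  # nearest-neighbour sampling quantises a translated set to the nearest
  # whole-voxel shift, biasing mask centroids by up to half a voxel
  mov_masks <- lapply(anat$structures$masks, function(m) {
    array(interp3(array(as.double(m), d), src_idx, background = 0), d) > 0.5
  })
  noises <- with_seed(spec$seed + 2000L, {
    list(ref = array(rnorm(prod(d), 0, spec$noise_sd), d),
         mov = array(rnorm(prod(d), 0, spec$noise_sd), d))
  })
  ref_img <- anat$volume$data
  if (spec$noise_sd > 0) {
    ref_img <- ref_img + noises$ref
    mov_img <- mov_img + noises$mov
  }
  structure(list(
    reference = list(volume = knee_volume(ref_img, spec$spacing),
                     structures = anat$structures),
    moving = list(volume = knee_volume(mov_img, spec$spacing),
                  structures = structure_set(mov_masks, spec$spacing)),
    truth_field = truth,
    truth_rigid = rig,
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> grid", paste(x$spec$grid_shape, collapse = "x"),
      "| side", x$spec$side, "| seed", x$spec$seed, "\n")
  cat("  medial motion (ML,AP,SI): ",
      paste(x$spec$meniscal_motion$medial, collapse = ", "), " mm\n", sep = "")
  cat("  lateral motion (ML,AP,SI): ",
      paste(x$spec$meniscal_motion$lateral, collapse = ", "), " mm\n", sep = "")
  invisible(x)
}
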