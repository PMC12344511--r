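# Shared phantom fixtures, generated in code and cached for the test run.
# Test problems use 48^3 grids at the study voxel scale (0.6 mm) so the
# whole suite stays fast; the geometry parameters scale the default anatomy
# into that field of view.

.fixture_cache <- new.env(parent = emptyenv())

MENISCUS_NAMES <- c("medial_meniscus", "lateral_meniscus")

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# geometry scaled into a 64x64x48 field of view with enough margin that the
# moving-scan menisci stay inside the grid under the largest rigid offsets
# and motions used in the tests
test_spec <- function(...) {
  args <- modifyList(list(grid_shape = c(64, 64, 48),
                          spacing = c(0.6, 0.6, 0.6),
                          meniscus_arc_radius = 6, compartment_offset = 6.5),
                     list(...))
  do.call(phantom_spec, args)
}

# a full default-motion case shared by several files
default_case <- function() cached("default_case", generate_case(test_spec(seed = 3)))

# rigid-offset-only case (no meniscal motion)
rigid_only_case <- function(seed = 5, offset = c(3, -2, 4, 2.5, -1, 0.5)) {
  cached(paste0("rigid_case_", seed), generate_case(test_spec(
    rigid_offset = offset,
    meniscal_motion = list(medial = c(0, 0, 0), lateral = c(0, 0, 0)),
    perturbation_amplitude = 0, seed = seed)))
}

# deformable-only case (no rigid offset), constant in-plane motions
deformable_case <- function() {
  cached("deformable_case", generate_case(test_spec(
    rigid_offset = rep(0, 6),
    meniscal_motion = list(medial = c(1.5, 0.5, 0), lateral = c(0.8, -1.2, 0.2)),
    perturbation_amplitude = 0, seed = 7)))
}

# its registration result, reused across solver/analysis tests
deformable_fit <- function() {
  cached("deformable_fit", {
    case <- deformable_case()
    register_multilevel(case$reference$volume, case$moving$volume,
                        case$reference$structures, case$moving$structures,
                        registration_control())
  })
}

mean_epe <- function(u, case, mask) {
  um <- matrix(u$vectors, ncol = 3)[which(mask), , drop = FALSE]
  tm <- matrix(case$truth_field$vectors, ncol = 3)[which(mask), , drop = FALSE]
  mean(sqrt(rowSums((um - tm)^2)))
}

meniscus_union <- function(structures) {
  structures$masks$medial_meniscus | structures$masks$lateral_meniscus
}

# Dice between the reference meniscus pushed forward by a field (approximated
# by backward warping with the negated field) and the moving meniscus
forward_warp_dice <- function(u, fixed_structures, moving_structures, nm) {
  neg <- deformation_field(-u$vectors, u$spacing, u$origin)
  m <- fixed_structures$masks[[nm]]
  wr <- warp_image(knee_volume(array(as.double(m), dim(m)),
                               fixed_structures$spacing,
                               fixed_structures$origin), neg)
  dice(wr$data > 0.5, moving_structures$masks[[nm]])
}

# small random objective-test problem on an 8^3 grid
tiny_problem <- function(seed = 42, spacing = c(1, 0.8, 1.2)) {
  set.seed(seed)
  d <- c(8, 8, 8)
  fixed <- knee_volume(array(rnorm(prod(d), 50, 10), d), spacing)
  moving <- knee_volume(array(rnorm(prod(d), 50, 10), d), spacing)
  region <- array(runif(prod(d)) < 0.4, d)
  mask <- array(FALSE, d)
  mask[3:6, 3:6, 3:6] <- TRUE
  dtm <- contour_distance_map(mask, spacing)
  pts <- mask_world_coords(menisci:::mask_surface(mask), spacing)
  u <- deformation_field(array(rnorm(prod(d) * 3, 0, 0.3), c(d, 3)), spacing)
  list(d = d, spacing = spacing, fixed = fixed, moving = moving,
       region = region, mask = mask, dt = dtm, points = pts, u = u)
}
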