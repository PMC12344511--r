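# Synthetic knee generator: geometry, determinism, ground-truth field
# construction and self-consistency of the simulated scan pair.

test_that("anatomy has six disjoint non-empty masks at plausible volumes", {
  spec <- test_spec(seed = 1)
  an <- build_anatomy(spec)
  masks <- an$structures$masks
  expect_setequal(names(masks),
                  c("femur", "tibia", "femoral_cartilage", "tibial_cartilage",
                    "medial_meniscus", "lateral_meniscus"))
  for (m in masks) expect_gt(sum(m), 0)
  total <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), dim(m))))
  expect_lte(max(total), 1L)
  # voxelised meniscus volume close to the analytic torus-segment volume
  analytic <- 2 * pi * spec$meniscus_arc_radius *
    (spec$meniscus_arc_span / 360) * pi * spec$meniscus_tube_radius^2
  voxelised <- sum(masks$medial_meniscus) * prod(spec$spacing)
  expect_lt(abs(voxelised - analytic) / analytic, 0.2)
})

test_that("noise is the only stochastic part of the anatomy", {
  a <- build_anatomy(test_spec(noise_sd = 0, seed = 1))
  b <- build_anatomy(test_spec(noise_sd = 0, seed = 99))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$structures$masks, b$structures$masks)
})

test_that("menisci are voxel-exact mirror images across the midline", {
  an <- build_anatomy(test_spec(meniscus_arc_span = 180, seed = 1),
                      noise = FALSE)
  med <- an$structures$masks$medial_meniscus
  lat <- an$structures$masks$lateral_meniscus
  expect_identical(med[dim(med)[1]:1, , ], lat)
})

test_that("truth field is the exact constant inside the menisci", {
  spec <- test_spec(rigid_offset = rep(0, 6),
                    meniscal_motion = list(medial = c(1.5, 0, 0),
                                           lateral = c(-0.4, 0.8, 0.2)),
                    perturbation_amplitude = 0, seed = 2)
  st <- build_anatomy(spec, noise = FALSE)$structures
  u <- make_truth_field(spec, st)
  um <- matrix(u$vectors, ncol = 3)
  # right knee: ML+ is +x, AP+ is -y, SI+ is +z
  med <- um[which(st$masks$medial_meniscus), , drop = FALSE]
  expect_equal(max(abs(sweep(med, 2, c(1.5, 0, 0)))), 0)
  lat <- um[which(st$masks$lateral_meniscus), , drop = FALSE]
  expect_equal(max(abs(sweep(lat, 2, c(-0.4, -0.8, 0.2)))), 0)

  zero_spec <- test_spec(meniscal_motion = list(medial = c(0, 0, 0),
                                                lateral = c(0, 0, 0)),
                         perturbation_amplitude = 0, seed = 2)
  u0 <- make_truth_field(zero_spec, st)
  expect_identical(max(abs(u0$vectors)), 0)
})

test_that("the perturbation stays within its amplitude but is non-trivial", {
  spec <- test_spec(meniscal_motion = list(medial = c(1, 0, 0),
                                           lateral = c(1, 0, 0)),
                    perturbation_amplitude = 0.3, seed = 11)
  st <- build_anatomy(spec, noise = FALSE)$structures
  u <- make_truth_field(spec, st)
  um <- matrix(u$vectors, ncol = 3)
  interior <- menisci:::erode_mask(st$masks$medial_meniscus, spec$spacing,
                                   min(spec$spacing)) |
    menisci:::erode_mask(st$masks$lateral_meniscus, spec$spacing,
                         min(spec$spacing))
  dev <- sweep(um[which(interior), , drop = FALSE], 2, c(1, 0, 0))
  mag <- sqrt(rowSums(dev^2))
  expect_lte(max(mag), 0.3 + 1e-12)
  expect_gt(max(mag), 0.15)
})

test_that("warping is exact for zero and one-voxel constant fields", {
  an <- build_anatomy(test_spec(seed = 4))
  vol <- an$volume
  d <- dim(vol$data)
  zero <- deformation_field(array(0, c(d, 3)), vol$spacing)
  expect_identical(warp_image(vol, zero)$data, vol$data)

  shift <- deformation_field(
    array(rep(c(vol$spacing[1], 0, 0), each = prod(d)), c(d, 3)), vol$spacing)
  w <- warp_image(vol, shift)$data
  # index-shift oracle on interior voxels
  expect_equal(w[1:(d[1] - 1), , ], vol$data[2:d[1], , ], tolerance = 1e-12)
})

test_that("warping by the negated smooth field approximately inverts", {
  d <- c(24, 24, 24)
  co <- (0:23) * 1.0
  g <- exp(-outer(outer((co - 12)^2, (co - 10)^2, `+`), (co - 13)^2, `+`) / 250)
  vol <- knee_volume(100 * g, c(1, 1, 1))
  set.seed(5)
  base <- array(rnorm(3, 0, 0.5), c(1, 1, 1, 3))
  u <- deformation_field(array(rep(base, each = prod(d)), c(d, 3)), vol$spacing)
  w <- warp_image(vol, u, background = 0)
  neg <- deformation_field(-u$vectors, vol$spacing)
  back <- warp_image(w, neg, background = 0)
  interior <- array(FALSE, d)
  interior[5:20, 5:20, 5:20] <- TRUE
  err <- abs(back$data - vol$data)[interior]
  expect_lt(max(err), 0.02 * diff(range(vol$data)))
})

test_that("case generation is a pure function of the spec", {
  spec <- test_spec(seed = 8)
  a <- generate_case(spec)
  b <- generate_case(spec)
  expect_identical(a$reference$volume$data, b$reference$volume$data)
  expect_identical(a$moving$volume$data, b$moving$volume$data)
  expect_identical(a$truth_field$vectors, b$truth_field$vectors)
})

test_that("a rigid-only pair is explained by the rigid transform alone", {
  case <- rigid_only_case()
  aligned <- resample_rigid(case$moving$volume, case$truth_rigid,
                            case$reference$volume, background = 20)
  men <- meniscus_union(case$reference$structures)
  resid <- abs(aligned$data - case$reference$volume$data)[men]
  expect_lt(mean(resid), 2 * case$spec$noise_sd)
})

test_that("the scan pair is self-consistent through the truth motion", {
  case <- default_case()
  # sample the moving scan at Rig(x + u(x)) in one composed step: it must
  # land on the reference anatomy (masks via Dice, intensities via
  # residuals within noise + interpolation tolerance)
  spc <- case$reference$volume$spacing
  d <- dim(case$reference$volume$data)
  world <- menisci:::index_to_world(menisci:::grid_index_matrix(d), spc,
                                    c(0, 0, 0))
  tgt <- transform_points(case$truth_rigid,
                          world + matrix(case$truth_field$vectors, ncol = 3))
  tgt_idx <- menisci:::world_to_index(tgt, spc, c(0, 0, 0))
  for (nm in MENISCUS_NAMES) {
    m <- case$moving$structures$masks[[nm]]
    wm <- array(menisci:::interp3(array(as.double(m), d), tgt_idx), d)
    expect_gte(dice(wm > 0.5, case$reference$structures$masks[[nm]]), 0.9)
  }
  warped <- array(menisci:::interp3(case$moving$volume$data, tgt_idx,
                                    background = 20), d)
  men <- meniscus_union(case$reference$structures)
  resid <- abs(warped - case$reference$volume$data)[men]
  expect_lt(mean(resid), 2 * case$spec$noise_sd)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(test_spec(meniscus_tube_radius = 7), "smaller than arc radius")
  expect_error(test_spec(meniscus_arc_span = 80), "90")
  expect_error(test_spec(rigid_offset = c(0, 0, 20, 0, 0, 0)), "10 degrees")
  expect_error(test_spec(meniscal_motion = list(medial = c(4, 0, 0),
                                                lateral = c(0, 0, 0))),
               "magnitude")
})
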