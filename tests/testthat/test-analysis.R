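# Motion analysis: field cropping, PCA frame conventions, equal-arc
# partitioning and per-compartment summaries.

canonical_frame <- function() {
  structure(list(ml_axis = c(1, 0, 0), ap_axis = c(0, 1, 0),
                 si_axis = c(0, 0, 1), provenance = "canonical test frame"),
            class = "coordinate_frame")
}

# C-shaped tube mask built independently of the phantom generator
c_tube_mask <- function(d, spacing, centre, R, r_tube, theta_range) {
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * spacing[ax])
  DX <- array(rep(co[[1]] - centre[1], times = d[2] * d[3]), d)
  DY <- array(rep(rep(co[[2]] - centre[2], each = d[1]), times = d[3]), d)
  DZ <- array(rep(co[[3]] - centre[3], each = d[1] * d[2]), d)
  rho <- sqrt(DX^2 + DY^2)
  theta <- atan2(DY, DX) * 180 / pi
  theta <- (theta - theta_range[1]) %% 360
  (rho - R)^2 + DZ^2 <= r_tube^2 &
    theta <= (theta_range[2] - theta_range[1]) %% 360
}

test_that("cropping retains exactly the meniscal vectors", {
  case <- default_case()
  fs <- case$reference$structures
  cf <- crop_field(case$truth_field, fs)
  n_men <- sum(meniscus_union(fs))
  expect_identical(nrow(cf$vectors), n_men)
  # brute-force masked mean
  med <- fs$masks$medial_meniscus
  expect_equal(colMeans(cf$vectors[cf$meniscus == "medial", ]),
               colMeans(matrix(case$truth_field$vectors, ncol = 3)[which(med), ]),
               tolerance = 1e-12)
  # a field supported outside the menisci crops to nothing
  d <- dim(med)
  outside <- array(0, c(d, 3))
  outside[, , , 1] <- !meniscus_union(fs)
  cf2 <- crop_field(deformation_field(outside, fs$spacing), fs)
  expect_identical(max(abs(cf2$vectors)), 0)
})

test_that("the PCA frame recovers the compartment axis of two C-tubes", {
  d <- c(80, 44, 12)
  sp <- c(1, 1, 1)
  med <- c_tube_mask(d, sp, centre = c(19, 20, 5), R = 12, r_tube = 2,
                     theta_range = c(80, 280))
  lat <- c_tube_mask(d, sp, centre = c(59, 20, 5), R = 12, r_tube = 2,
                     theta_range = c(260, 100))
  st <- structure_set(list(medial_meniscus = med, lateral_meniscus = lat), sp)
  fr <- compute_axes(st)
  # brute-force covariance eigendecomposition of the pooled point set
  pts <- rbind(mask_world_coords(med, sp), mask_world_coords(lat, sp))
  ev <- eigen(cov(pts), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(fr$ml_axis * ev)), cos(5 * pi / 180))
  expect_gt(abs(fr$ml_axis[1]), cos(5 * pi / 180)) # within 5 deg of grid x
  expect_gt(sum(fr$ml_axis * c(1, 0, 0)), 0)       # medial -> lateral
  expect_lt(fr$ap_axis[2], 0)                      # + towards posterior (-y)
  # orthonormal right-handed frame
  M <- cbind(fr$ml_axis, fr$ap_axis, fr$si_axis)
  expect_lt(max(abs(crossprod(M) - diag(3))), 1e-8)
  expect_equal(det(M), 1, tolerance = 1e-8)
})

test_that("frames keep lateral-positive semantics for left and right knees", {
  for (side in c("right", "left")) {
    spec <- test_spec(side = side, rigid_offset = rep(0, 6),
                      meniscal_motion = list(medial = c(1, 0, 0),
                                             lateral = c(1, 0, 0)),
                      perturbation_amplitude = 0, seed = 12)
    case <- generate_case(spec)
    fs <- case$reference$structures
    fr <- compute_axes(fs)
    cf <- crop_field(case$truth_field, fs)
    parts <- list(
      medial = partition_meniscus(fs$masks$medial_meniscus, fr, fs$spacing),
      lateral = partition_meniscus(fs$masks$lateral_meniscus, fr, fs$spacing))
    sm <- summarize_motion(cf, parts, fr)
    # truth motion is +1 mm lateral on both menisci: every ML entry positive
    expect_true(all(sm$ml_mm > 0.9))
    expect_lt(max(abs(sm$ap_mm)), 0.1)
  }
})

test_that("equal-arc partition of a semicircular tube has equal thirds", {
  d <- c(56, 40, 9)
  sp <- c(1, 1, 1)
  mask <- c_tube_mask(d, sp, centre = c(27, 8, 4), R = 20, r_tube = 2,
                      theta_range = c(0, 180))
  part <- partition_meniscus(mask, canonical_frame(), sp)
  expect_identical(length(part$labels), sum(mask))
  expect_identical(sort(unique(as.character(part$labels))),
                   c("AH", "IP", "PH"))
  # the three centerline thirds each measure (pi*20)/3 within one voxel
  total <- max(part$arclength)
  thirds <- c(part$cut_arclengths[1], diff(part$cut_arclengths),
              total - part$cut_arclengths[2])
  expect_lt(max(abs(thirds - pi * 20 / 3)), max(sp))
  # symmetric C: end segments nearly equal voxel counts
  counts <- table(part$labels)
  expect_lt(abs(counts[["AH"]] - counts[["PH"]]) / counts[["AH"]], 0.1)
  # deterministic relabelling
  part2 <- partition_meniscus(mask, canonical_frame(), sp)
  expect_identical(part$labels, part2$labels)
})

test_that("partition labels follow the anatomy under in-plane rotation", {
  d <- c(64, 64, 9)
  sp <- c(1, 1, 1)
  centre <- c(31, 31, 4)
  for (rot in c(0, 30)) {
    mask <- c_tube_mask(d, sp, centre, R = 20, r_tube = 2,
                        theta_range = c(20, 200) + rot)
    part <- partition_meniscus(mask, canonical_frame(), sp)
    pts <- mask_world_coords(mask, sp)
    ang <- (atan2(pts[, 2] - centre[2], pts[, 1] - centre[1]) * 180 / pi -
              20 - rot) %% 360 # material arc parameter in [0, 180]
    # label boundaries in material angle must sit at the arc thirds,
    # independent of the grid rotation
    for (lab in c("AH", "IP", "PH")) {
      rng <- range(ang[part$labels == lab])
      expect_lt(min(abs(rng[1] - c(0, 60, 120))), 7.5)
      expect_lt(min(abs(rng[2] - c(60, 120, 180))), 7.5)
    }
  }
})

test_that("non-C-shaped or fragmented masks are rejected", {
  d <- c(24, 24, 8)
  sp <- c(1, 1, 1)
  two <- array(FALSE, d)
  two[3:6, 3:6, 3:5] <- TRUE
  two[15:18, 15:18, 3:5] <- TRUE
  expect_error(partition_meniscus(two, canonical_frame(), sp),
               "connected components")
  stub <- c_tube_mask(d, sp, c(11, 11, 4), R = 8, r_tube = 2,
                      theta_range = c(0, 40))
  expect_error(partition_meniscus(stub, canonical_frame(), sp), "90 deg")
})

test_that("summaries project mean motion onto the anatomical axes", {
  case <- default_case()
  fs <- case$reference$structures
  fr <- compute_axes(fs)
  parts <- list(
    medial = partition_meniscus(fs$masks$medial_meniscus, fr, fs$spacing),
    lateral = partition_meniscus(fs$masks$lateral_meniscus, fr, fs$spacing))
  d <- dim(fs$masks$medial_meniscus)
  const_field <- function(v_world) {
    deformation_field(array(rep(v_world, each = prod(d)), c(d, 3)),
                      fs$spacing)
  }
  # 1 mm along the ML axis: Avg 1, ML +1, AP 0 in every scope
  sm1 <- summarize_motion(crop_field(const_field(fr$ml_axis), fs), parts, fr)
  expect_equal(sm1$avg_mm, rep(1, 8), tolerance = 1e-9)
  expect_equal(sm1$ml_mm, rep(1, 8), tolerance = 1e-9)
  expect_equal(sm1$ap_mm, rep(0, 8), tolerance = 1e-9)
  # 3-4-5 vector in frame coordinates: Avg exactly 1
  sm2 <- summarize_motion(crop_field(
    const_field(0.6 * fr$ml_axis + 0.8 * fr$ap_axis), fs), parts, fr)
  expect_equal(sm2$avg_mm, rep(1, 8), tolerance = 1e-9)
  expect_equal(sm2$ml_mm, rep(0.6, 8), tolerance = 1e-9)
  expect_equal(sm2$ap_mm, rep(0.8, 8), tolerance = 1e-9)
  # Avg is the norm of (ML, AP, SI) by definition, hence >= sqrt(ML^2+AP^2)
  expect_equal(sm2$avg_mm,
               sqrt(sm2$ml_mm^2 + sm2$ap_mm^2 + sm2$si_mm^2),
               tolerance = 1e-9)
})

test_that("piecewise fields average per compartment and pool by voxel count", {
  case <- default_case()
  fs <- case$reference$structures
  fr <- compute_axes(fs)
  parts <- list(
    medial = partition_meniscus(fs$masks$medial_meniscus, fr, fs$spacing),
    lateral = partition_meniscus(fs$masks$lateral_meniscus, fr, fs$spacing))
  d <- dim(fs$masks$medial_meniscus)
  u <- array(0, c(d, 3))
  um <- matrix(u, ncol = 3)
  pm <- parts$medial
  ah <- pm$lin[pm$labels == "AH"]
  ph <- pm$lin[pm$labels == "PH"]
  um[ah, ] <- matrix(fr$ml_axis, length(ah), 3, byrow = TRUE)
  um[ph, ] <- matrix(-fr$ml_axis, length(ph), 3, byrow = TRUE)
  field <- deformation_field(array(um, c(d, 3)), fs$spacing)
  sm <- summarize_motion(crop_field(field, fs), parts, fr)
  mm <- sm[sm$meniscus == "MM", ]
  expect_equal(mm$ml_mm[mm$scope == "AH"], 1, tolerance = 1e-9)
  expect_equal(mm$ml_mm[mm$scope == "PH"], -1, tolerance = 1e-9)
  expect_equal(mm$ml_mm[mm$scope == "IP"], 0, tolerance = 1e-9)
  n <- sum(fs$masks$medial_meniscus)
  expect_equal(mm$ml_mm[mm$scope == "Overall"],
               (length(ah) - length(ph)) / n, tolerance = 1e-9)
  # per-voxel-norm alternative is bounded below by the vector-mean Avg
  smn <- summarize_motion(crop_field(field, fs), parts, fr,
                          per_voxel_norm = TRUE)
  expect_true(all(smn$avg_mm >= sm$avg_mm - 1e-12))
})

test_that("summaries round-trip through CSV and aggregate across cases", {
  case <- default_case()
  fs <- case$reference$structures
  fr <- compute_axes(fs)
  parts <- list(
    medial = partition_meniscus(fs$masks$medial_meniscus, fr, fs$spacing),
    lateral = partition_meniscus(fs$masks$lateral_meniscus, fr, fs$spacing))
  sm <- summarize_motion(crop_field(case$truth_field, fs), parts, fr)
  expect_identical(nrow(sm), 8L)
  path <- tempfile(fileext = ".csv")
  write_summary(sm, path)
  back <- read_summary(path)
  for (col in c("avg_mm", "ml_mm", "ap_mm", "si_mm"))
    expect_equal(back[[col]], sm[[col]], tolerance = 1e-9)

  s2 <- sm; s2$ml_mm <- s2$ml_mm + 0.5
  s3 <- sm; s3$ml_mm <- s3$ml_mm - 0.2
  agg <- aggregate_cohort(list(sm, s2, s3))
  i <- agg$meniscus == "MM" & agg$scope == "Overall"
  vals <- c(sm$ml_mm[1], s2$ml_mm[1], s3$ml_mm[1])
  expect_equal(agg$ml_mm_mean[i], mean(vals), tolerance = 1e-12)
  expect_equal(agg$ml_mm_sd[i], sd(vals), tolerance = 1e-12)
  expect_identical(agg$n_cases[i], 3L)
})
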