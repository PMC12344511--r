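# Tibia-masked rigid alignment: transform algebra, resampling fidelity and
# recovery of known offsets.

test_that("rigid transform algebra is consistent", {
  t1 <- rigid_transform(c(3, -2, 5), c(2, -1, 0.5), center = c(10, 12, 8))
  R <- menisci:::rotation_matrix(t1$rotation)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)

  set.seed(1)
  pts <- matrix(runif(60, 0, 30), ncol = 3) # grid-bounding-box sized
  there <- transform_points(t1, pts)
  back <- transform_points(rigid_inverse(t1), there)
  expect_lt(max(abs(back - pts)), 1e-8)

  t2 <- rigid_transform(c(-1, 2, 1), c(0.5, 0.2, -1), center = c(0, 5, 0))
  comp <- rigid_compose(t1, t2)
  expect_lt(max(abs(transform_points(comp, pts) -
                      transform_points(t1, transform_points(t2, pts)))), 1e-8)

  recentred <- rigid_with_center(t1, c(0, 0, 0))
  expect_lt(max(abs(transform_points(recentred, pts) -
                      transform_points(t1, pts))), 1e-8)
})

test_that("resampling through identity and inverse transforms is faithful", {
  case <- rigid_only_case()
  vol <- case$reference$volume
  st <- case$reference$structures
  ident <- rigid_transform()
  expect_equal(resample_rigid(vol, ident)$data, vol$data, tolerance = 1e-12)
  expect_identical(resample_rigid(st, ident)$masks, st$masks)

  tr <- rigid_transform(c(2, -3, 4), c(2, 1, -1.5),
                        center = colMeans(mask_world_coords(st$masks$tibia,
                                                            st$spacing)))
  roundtrip <- resample_rigid(resample_rigid(st, tr), rigid_inverse(tr))
  # the femur is truncated by the test field of view, so rotation carries
  # part of it off-grid; the 1.2 mm cartilage shells are only two voxels
  # thick, where boundary re-thresholding costs a few percent of Dice
  for (nm in c("tibia", "medial_meniscus", "lateral_meniscus"))
    expect_gte(dice(roundtrip$masks[[nm]], st$masks[[nm]]), 0.98)
  for (nm in c("femoral_cartilage", "tibial_cartilage"))
    expect_gte(dice(roundtrip$masks[[nm]], st$masks[[nm]]), 0.95)

  # exactly one voxel of translation shifts mask indices exactly
  one_vox <- rigid_transform(translation = c(vol$spacing[1], 0, 0))
  shifted <- resample_rigid(st, one_vox)
  d <- dim(st$masks$tibia)
  expect_identical(shifted$masks$tibia[1:(d[1] - 1), , ],
                   st$masks$tibia[2:d[1], , ])
})

test_that("registering an image to itself yields the identity", {
  case <- rigid_only_case()
  fx <- case$reference$volume
  est <- register_rigid_masked(fx, fx, case$reference$structures$masks$tibia,
                               levels = 2)
  expect_lt(max(abs(est$rotation)), 0.05)
  expect_lt(max(abs(est$translation)), 0.05)
})

test_that("known translations and rotations are recovered", {
  case <- rigid_only_case()
  fx <- case$reference$volume
  tib <- case$reference$structures$masks$tibia
  ctr <- colMeans(mask_world_coords(tib, fx$spacing))

  tr <- rigid_transform(translation = c(2, -1, 0.5), center = ctr)
  moved <- resample_rigid(fx, tr, fx, background = 20)
  est <- register_rigid_masked(fx, moved, tib)
  # moved(x) = fixed(tr(x)) => registering fixed->moved recovers tr^{-1}
  truth <- rigid_with_center(rigid_inverse(tr), est$center)
  expect_lt(max(abs(est$translation - truth$translation)), 0.1)
  expect_lt(max(abs(est$rotation - truth$rotation)), 0.2)

  rot <- rigid_transform(rotation = c(0, 0, 5), center = ctr)
  moved2 <- resample_rigid(fx, rot, fx, background = 20)
  est2 <- register_rigid_masked(fx, moved2, tib)
  truth2 <- rigid_with_center(rigid_inverse(rot), est2$center)
  expect_lt(max(abs(est2$rotation - truth2$rotation)), 0.2)
  expect_lt(max(abs(est2$translation - truth2$translation)), 0.1)
})

test_that("whole-leg repositioning in a simulated pair is recovered", {
  case <- rigid_only_case()
  est <- register_rigid_masked(case$reference$volume, case$moving$volume,
                               case$reference$structures$masks$tibia)
  truth <- rigid_with_center(case$truth_rigid, est$center)
  expect_lt(max(abs(est$rotation - truth$rotation)), 0.2)
  expect_lt(max(abs(est$translation - truth$translation)), 0.1)
})

test_that("intensities outside the tibia mask have no influence", {
  case <- rigid_only_case()
  fx <- case$reference$volume
  tib <- case$reference$structures$masks$tibia
  est1 <- register_rigid_masked(fx, case$moving$volume, tib)
  far <- menisci:::surface_distance(tib, fx$spacing) > 5
  perturbed <- fx
  set.seed(9)
  perturbed$data[far] <- perturbed$data[far] + rnorm(sum(far), 0, 50)
  est2 <- register_rigid_masked(perturbed, case$moving$volume, tib)
  expect_lt(max(abs(est1$rotation - est2$rotation)), 0.01)
  expect_lt(max(abs(est1$translation - est2$translation)), 0.01)
})

test_that("an empty tibia mask is rejected", {
  case <- rigid_only_case()
  empty <- array(FALSE, dim(case$reference$volume$data))
  expect_error(register_rigid_masked(case$reference$volume,
                                     case$moving$volume, empty), "empty")
})
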