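# Volume, mask and field I/O: lossless round trips, grid fidelity, and
# rejection of malformed inputs.

test_that("volumes round-trip through NIfTI with exact data and grid", {
  set.seed(1)
  vol <- knee_volume(array(rnorm(16^3, 100, 20), c(16, 16, 16)),
                     spacing = c(0.5, 0.6, 0.6), origin = c(1, -2, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-12)
  expect_equal(back$spacing, c(0.5, 0.6, 0.6))
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
})

test_that("study-protocol anisotropic spacing is preserved exactly", {
  # 0.6 mm AP x 0.5 mm RL x 0.6 mm FH acquisition grid: canonical axis
  # order is (RL, AP, FH)
  vol <- knee_volume(array(0, c(8, 8, 8)), spacing = c(0.5, 0.6, 0.6))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  expect_identical(read_volume(path)$spacing, c(0.5, 0.6, 0.6))
})

test_that("flipped-axis headers are reoriented to the canonical frame", {
  set.seed(2)
  a <- array(rnorm(6 * 8 * 10), c(6, 8, 10))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(0.5, 0.6, 0.7)
  aff <- diag(c(-0.5, 0.6, 0.7, 1))
  aff[1:3, 4] <- c(4.5, 2, 3) # +x column negated: an LAS-style header
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  vol <- read_volume(path)
  # independent decomposition of the affine: x axis was flipped, so the
  # canonical array is the x-reversed input with origin at the low corner
  expect_identical(attr(vol, "source_orientation"), "LAS")
  expect_equal(vol$data, a[6:1, , ], tolerance = 1e-12)
  expect_equal(vol$origin, c(4.5 - 0.5 * 5, 2, 3), tolerance = 1e-5)
})

test_that("vector-valued input is rejected as a scalar volume", {
  img <- RNifti::asNifti(array(0, c(8, 8, 8, 3)))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "4 dimensions")
  expect_error(read_volume(tempfile(fileext = ".nii.gz")), "not found")
})

test_that("MetaImage dialect round-trips volumes", {
  set.seed(3)
  vol <- knee_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)),
                     spacing = c(1, 0.8, 1.2), origin = c(-1, 0, 2))
  path <- tempfile(fileext = ".mha")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-12)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
})

test_that("a single label image splits into per-structure masks", {
  an <- build_anatomy(test_spec(seed = 2), noise = FALSE)
  labels <- seq_along(an$structures$masks)
  names(labels) <- names(an$structures$masks)
  lab_img <- array(0, dim(an$volume$data))
  for (nm in names(labels)) lab_img[an$structures$masks[[nm]]] <- labels[[nm]]
  path <- tempfile(fileext = ".nii.gz")
  write_volume(knee_volume(lab_img, an$volume$spacing), path)
  companion <- knee_volume(array(0, dim(lab_img)), an$volume$spacing)
  st <- read_structures(path, companion, labels = labels)
  # the masks partition the nonzero voxels of the label image
  expect_equal(sum(vapply(st$masks, sum, numeric(1))), sum(lab_img != 0))
  for (nm in names(labels))
    expect_identical(st$masks[[nm]], an$structures$masks[[nm]])
})

test_that("structure sets round-trip through per-structure files", {
  st <- build_anatomy(test_spec(seed = 2), noise = FALSE)$structures
  dir <- tempfile()
  paths <- write_structures(st, dir)
  companion <- knee_volume(array(0, dim(st$masks[[1]])), st$spacing)
  back <- read_structures(paths, companion)
  expect_identical(back$masks, st$masks)
})

test_that("grid mismatches are rejected rather than resampled", {
  companion <- knee_volume(array(0, c(10, 10, 10)), c(1, 1, 1))
  small <- knee_volume(array(1, c(10, 10, 9)), c(1, 1, 1))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(small, path)
  expect_error(read_structures(c(tibia = path), companion), "does not match")
})

test_that("deformation fields round-trip losslessly", {
  d <- c(12, 10, 8)
  zero <- deformation_field(array(0, c(d, 3)), c(0.6, 0.5, 0.6))
  p1 <- tempfile(fileext = ".nii.gz")
  write_field(zero, p1)
  expect_identical(max(abs(read_field(p1)$vectors)), 0)

  set.seed(7)
  f <- deformation_field(array(runif(prod(d) * 3, -2, 2), c(d, 3)),
                         c(0.6, 0.5, 0.6), origin = c(1, 2, 3))
  p2 <- tempfile(fileext = ".nii.gz")
  write_field(f, p2)
  back <- read_field(p2)
  expect_lt(max(abs(back$vectors - f$vectors)), 1e-6)
  expect_equal(back$spacing, f$spacing)

  # attaching to a different grid must fail
  other <- knee_volume(array(0, c(12, 10, 9)), c(0.6, 0.5, 0.6))
  expect_error(read_field(p2, reference = other), "grid mismatch")

  p3 <- tempfile(fileext = ".mha")
  write_field(f, p3)
  expect_lt(max(abs(read_field(p3)$vectors - f$vectors)), 1e-6)
})
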