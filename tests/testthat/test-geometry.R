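test_that("world/voxel mappings are exact inverses", {
  vol <- pvr_volume(array(0, c(10, 12, 8)), spacing = c(1.25, 1.25, 2.5),
                    origin = c(-5, -5, -4))
  expect_equal(voxel_to_world(vol, c(0, 0, 0)), c(-5, -5, -4))
  expect_equal(world_to_voxel(vol, c(-5, -5, -4)), c(0, 0, 0))
  # forward map of a named index
  w <- vol$origin + vol$direction %*% (vol$spacing * c(2, 3, 4))
  expect_equal(world_to_voxel(vol, as.numeric(w)), c(2, 3, 4))
  set.seed(1)
  v <- matrix(runif(300, -5, 15), ncol = 3)
  rt <- world_to_voxel(vol, voxel_to_world(vol, v))
  expect_lt(max(abs(rt - v)), 1e-9)
  # indices outside the grid are returned, not clamped
  expect_equal(world_to_voxel(vol, c(-5 - 1.25, -5, -4)), c(-1, 0, 0))
})

test_that("volume validation rejects bad geometry", {
  expect_error(pvr_volume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(pvr_volume(array(0, c(4, 4, 4)), c(1, -1, 1)), "spacing")
  expect_error(pvr_volume(array(0, c(4, 4, 4)), direction = matrix(1, 3, 3)),
               "orthonormal")
})

test_that("rigid transforms compose, invert, and rebase exactly", {
  set.seed(2)
  for (i in 1:100) {
    tr <- random_rigid()
    p <- matrix(rnorm(15), ncol = 3)
    back <- apply_transform(invert_transform(tr), apply_transform(tr, p))
    expect_lt(max(abs(back - p)), 1e-9)
  }
  # associativity through the matrix representation
  a <- random_rigid(); b <- random_rigid(); c <- random_rigid()
  m1 <- as_affine_matrix(compose_transforms(compose_transforms(a, b), c))
  m2 <- as_affine_matrix(compose_transforms(a, compose_transforms(b, c)))
  expect_lt(max(abs(m1 - m2)), 1e-9)
  # rebasing the centre leaves the mapping untouched
  tr <- random_rigid()
  tr2 <- pvr:::rebase_center(tr, c(5, -3, 7))
  p <- matrix(rnorm(30), ncol = 3)
  expect_lt(max(abs(apply_transform(tr, p) - apply_transform(tr2, p))), 1e-9)
})

test_that("affine transforms validate and invert", {
  expect_error(affine_transform(diag(3)), "4x4")
  m <- diag(4); m[1:3, 1:3] <- matrix(c(1, .2, 0, .2, 1, 0, 0, 0, 1), 3)
  af <- affine_transform(m)
  p <- matrix(rnorm(30), ncol = 3)
  back <- apply_transform(invert_transform(af), apply_transform(af, p))
  expect_lt(max(abs(back - p)), 1e-9)
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(affine_transform(sing), "singular")
})

test_that("resampling honours identity, lattice shifts, and round trips", {
  ph <- phantom48()
  r <- resample(ph, ph, NULL, "nearest")
  expect_identical(r$voxels, ph$voxels)
  r2 <- resample(ph, ph, NULL, "linear")
  expect_lt(max(abs(r2$voxels - ph$voxels)), 1e-12)
  # pure integer-voxel translation with nearest interpolation: exact shift
  tr <- rigid_transform(translation = c(2, 0, 0) * ph$spacing[1])
  sh <- resample(ph, ph, tr, "nearest")
  expect_identical(sh$voxels[3:48, , ], ph$voxels[1:46, , ])
  # t then -t with linear interpolation on a smooth volume: small error
  # away from the boundary (linear-interpolation error scales with the
  # field's curvature, so a band-limited field is used)
  g <- seq(0, 2 * pi, length.out = 48)
  sm <- pvr_volume(500 + 400 * outer(outer(sin(g), cos(1.5 * g)),
                                     sin(0.5 * g + 1)))
  t1 <- resample(sm, sm, rigid_transform(translation = c(0.4, -0.3, 0.6)))
  t2 <- resample(t1, sm, rigid_transform(translation = -c(0.4, -0.3, 0.6)))
  core <- 5:44
  err <- max(abs(t2$voxels[core, core, core] - sm$voxels[core, core, core]))
  expect_lt(err, 0.01 * diff(range(sm$voxels)))
})

test_that("resampling a constant image returns the constant in-field", {
  vol <- pvr_volume(array(7.5, c(12, 12, 12)))
  tr <- random_rigid(rot_max = 30, trans_max = 3, center_max = 5)
  r <- resample(vol, vol, tr, "linear", background = -1)
  inf <- attr(r, "infield")
  expect_true(all(abs(r$voxels[inf] - 7.5) < 1e-12))
  expect_true(all(r$voxels[!inf] == -1))
})

test_that("NIfTI round trip preserves geometry and voxels", {
  vol <- pvr_volume(array(rnorm(8 * 6 * 4), c(8, 6, 4)),
                    spacing = c(1.25, 1.25, 2.5), origin = c(-4, -3, -5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$voxels, vol$voxels, tolerance = 1e-7)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_equal(back$direction, vol$direction, tolerance = 1e-6)
})

test_that("transform text files round trip", {
  tr <- rigid_transform(c(1.5, -2, 3), c(0.1, 0.2, -0.3), c(5, 5, 5))
  f <- tempfile(fileext = ".txt")
  write_transform(tr, f)
  back <- read_transform(f)
  expect_equal(back$rotation, tr$rotation)
  expect_equal(back$translation, tr$translation)
  expect_equal(back$center, tr$center)
  af <- skew_matrix(1, c(1, 2, 3))
  write_transform(af, f)
  expect_equal(as_affine_matrix(read_transform(f)), as_affine_matrix(af))
})
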