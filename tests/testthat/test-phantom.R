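test_that("phantom generation is deterministic and featured", {
  a <- make_phantom(48, 1, seed = 9)
  b <- make_phantom(48, 1, seed = 9)
  expect_identical(a$voxels, b$voxels)
  c <- make_phantom(48, 1, seed = 10)
  expect_false(identical(a$voxels, c$voxels))
  expect_error(make_phantom(16), "at least 32")
  # distinct intensity modes: background plus >= 2 tissue classes
  h <- hist(a$voxels[a$voxels > 0], breaks = seq(0, 1000, by = 50),
            plot = FALSE)
  interior_peaks <- sum(diff(sign(diff(h$counts))) == -2)
  expect_gte(sum(a$voxels == 0), 1000)   # background mode
  expect_gte(interior_peaks, 2)          # >= 2 tissue modes on top
  # generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_phantom(32, 1, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("skew matrix carries one combined shear value", {
  m <- as_affine_matrix(skew_matrix(1))
  off <- m[1:3, 1:3][row(diag(3)) != col(diag(3))]
  expect_equal(off, rep(tan(pi / 180), 6))
  expect_equal(as_affine_matrix(skew_matrix(0)), diag(4))
  expect_error(motion_spec("skew", theta_xyz = 45), "45")
})

test_that("apply_motion implements the three corruption kinds", {
  ph <- phantom48()
  # zero skew is the identity
  out <- apply_motion(ph, motion_spec("skew", theta_xyz = 0))
  expect_lt(max(abs(out$voxels - ph$voxels)), 1e-9)
  # rigid translation moves mass along x only
  tr <- apply_motion(ph, motion_spec("rigid_translation", d_x = 3),
                     interpolation = "nearest")
  expect_identical(tr$voxels[4:48, , ], ph$voxels[1:45, , ])
  # bulk rotation: lower half bitwise unchanged with nearest interpolation
  bk <- apply_motion(ph, motion_spec("bulk_rotation", theta_z = 10),
                     interpolation = "nearest")
  expect_identical(bk$voxels[, , 1:24], ph$voxels[, , 1:24])
  expect_false(identical(bk$voxels[, , 25:48], ph$voxels[, , 25:48]))
  # linear interpolation introduces no new extrema
  sk <- apply_motion(ph, motion_spec("skew", theta_xyz = 2))
  expect_gte(min(sk$voxels), min(ph$voxels))
  expect_lte(max(sk$voxels), max(ph$voxels))
})

test_that("interleaved sampling alternates sources on the stack grid", {
  ph <- phantom48()
  cor <- apply_motion(ph, motion_spec("rigid_translation", d_x = 4))
  st <- sample_interleaved_stack(ph, cor, stack_spec("axial"))
  expect_equal(st$spacing, c(1.25, 1.25, 2.5))
  # degenerate: corrupted == free makes interleaving invisible
  s1 <- sample_interleaved_stack(ph, ph, stack_spec("sagittal"))
  s2 <- sample_interleaved_stack(ph, cor, stack_spec(
    "sagittal", interleave_pattern = rep("free", vol_dim(s1)[3])))
  expect_identical(s1$voxels, s2$voxels)
  # interleaved slices genuinely differ from the all-free stack
  pat <- attr(st, "pattern")
  all_free <- sample_interleaved_stack(ph, ph, stack_spec("axial"))
  diffs <- vapply(seq_along(pat), function(k)
    max(abs(st$voxels[, , k] - all_free$voxels[, , k])), numeric(1))
  expect_true(all(diffs[pat == "free"] == 0))
  expect_true(any(diffs[pat == "corrupted"] > 0))
  # geometry mismatch is refused
  other <- make_phantom(32, 1.5, seed = 1)
  expect_error(sample_interleaved_stack(ph, other, stack_spec("axial")),
               "geometry")
  # wrong pattern length is refused
  expect_error(sample_interleaved_stack(ph, cor, stack_spec(
    "axial", interleave_pattern = c("free", "corrupted"))), "length")
})

test_that("simulate_study produces the standard three-stack experiment", {
  study <- study48_skew()
  expect_length(study$stacks, 3)
  for (st in study$stacks)
    expect_equal(st$spacing, c(1.25, 1.25, 2.5))
  dirs <- vapply(study$stacks, function(s) which.max(abs(s$direction[, 3])),
                 integer(1))
  expect_setequal(dirs, c(3, 1, 2))  # axial, sagittal, coronal slice axes
})
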