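test_that("template selection prefers the least motion-corrupted stack", {
  st <- stack96()
  expect_equal(select_template_stack(list(st)), 1L)
  expect_equal(select_template_stack(list(st, st)), 1L)  # tie -> lowest index
  noisy <- st
  set.seed(3)
  ks <- seq(1, dim(noisy$voxels)[3], by = 2)
  noisy$voxels[, , ks] <- array(runif(prod(dim(noisy$voxels)[1:2]) *
                                        length(ks), 0, 1000),
                                c(dim(noisy$voxels)[1:2], length(ks)))
  expect_equal(select_template_stack(list(noisy, st)), 2L)
  expect_error(select_template_stack(list()), "at least one")
})

test_that("intensity matching recovers pure gains", {
  st <- stack96()
  expect_identical(match_intensities(list(st), 1L)[[1]]$voxels, st$voxels)
  doubled <- st; doubled$voxels <- 2 * st$voxels
  out <- match_intensities(list(st, doubled), 1L)
  expect_equal(attr(out, "gains"), c(1, 0.5))
  expect_equal(out[[2]]$voxels, st$voxels, tolerance = 1e-12)
  # several random gains: all foreground medians agree afterwards
  set.seed(8)
  gains <- runif(5, 0.5, 2)
  stacks <- lapply(gains, function(g) { s <- st; s$voxels <- g * s$voxels; s })
  matched <- match_intensities(stacks, 1L)
  meds <- vapply(matched, pvr:::foreground_median, numeric(1))
  expect_lt(max(abs(meds - meds[1])), 1e-6)
  zero <- st; zero$voxels[] <- 0
  expect_error(match_intensities(list(st, zero), 1L), "foreground")
})

test_that("3D-3D registration recovers known rigid motions", {
  ph <- phantom48()
  res0 <- register_volume_3d(ph, ph)
  expect_lt(max(abs(res0$transform$rotation)), 0.1)
  expect_lt(max(abs(res0$transform$translation)), 0.1)
  mv <- resample(ph, ph, rigid_transform(translation = c(3, -2, 4)))
  res <- register_volume_3d(mv, ph)
  expect_lt(max(abs(res$transform$translation - c(-3, 2, -4))), 0.5)
  expect_lt(max(abs(res$transform$rotation)), 0.5)
  rot <- resample(ph, ph, rigid_transform(rotation = c(0, 0, 5),
                                          center = c(0, 0, 0)))
  res2 <- register_volume_3d(rot, ph)
  expect_lt(abs(res2$transform$rotation[3] + 5), 0.5)
  # symmetric quality: A->B composed with B->A is the identity
  res_ab <- register_volume_3d(mv, ph)
  res_ba <- register_volume_3d(ph, mv)
  comp <- compose_transforms(res_ba$transform, res_ab$transform)
  p <- matrix(rnorm(30, sd = 10), ncol = 3)
  expect_lt(max(abs(apply_transform(comp, p) - p)), 1)
})

test_that("patch registration honours its warm-start contract", {
  ph <- phantom96()
  st <- stack96()
  d <- vol_dim(st)
  psf <- psf_model(st$spacing[1:2], st$spacing[3])
  pix <- as.matrix(expand.grid(22:53, 22:53))
  y <- st$voxels[, , 16][pix + 1]
  p <- new_patch(1, 15L, pix, y)
  ctr <- colMeans(voxel_to_world(st, cbind(pix, 15L)))
  p$transform <- rigid_transform(center = ctr)
  # perfect volume, unmoved patch: stays at the stack transform
  res <- register_patch_to_volume(p, ph, st, psf)
  expect_true(res$converged)
  expect_lt(max(abs(res$transform$rotation)), 0.2)
  expect_lt(max(abs(res$transform$translation)), 0.25)
  # similarity never drops below the warm start's
  p2 <- p
  p2$transform <- rigid_transform(c(1, -1, 2), c(1, 0.5, -1), ctr)
  f0 <- pvr:::cc_patch_pose(ph, st, pvr:::patch_pixel_matrix(p2), p2$y,
                            c(p2$transform$rotation,
                              p2$transform$translation), ctr, 0.5)
  res2 <- register_patch_to_volume(p2, ph, st, psf)
  expect_gte(res2$similarity, f0)
  # degenerate variance: skipped, warm start retained
  pf <- p
  pf$y[] <- 1
  pf$registrable <- FALSE
  res3 <- register_patch_to_volume(pf, ph, st, psf)
  expect_false(res3$converged)
  expect_equal(res3$transform$rotation, p$transform$rotation)
})

test_that("a known in-plane displacement is recovered within half a mm", {
  ph <- phantom96()
  st <- stack96()
  psf <- psf_model(st$spacing[1:2], st$spacing[3])
  pix <- as.matrix(expand.grid(22:53, 22:53))
  y <- st$voxels[, , 16][pix + 1]
  p <- new_patch(1, 15L, pix, y)
  ctr <- colMeans(voxel_to_world(st, cbind(pix, 15L)))
  # displace by 2 mm in-plane before registration
  p$transform <- rigid_transform(c(0, 0, 0), c(2, 0, 0), ctr)
  res <- register_patch_to_volume(p, ph, st, psf, profile = "robust")
  expect_lt(max(abs(res$transform$translation)), 0.5)
  expect_lt(max(abs(res$transform$rotation)), 1)
})

test_that("psf-simulated similarity mode agrees at the optimum", {
  ph <- phantom96()
  st <- stack96()
  psf <- psf_model(st$spacing[1:2], st$spacing[3])
  pix <- as.matrix(expand.grid(22:45, 22:45))
  y <- st$voxels[, , 16][pix + 1]
  p <- new_patch(1, 15L, pix, y)
  ctr <- colMeans(voxel_to_world(st, cbind(pix, 15L)))
  p$transform <- rigid_transform(c(0.5, -0.5, 0.5), c(0.5, -0.5, 0.5), ctr)
  res <- register_patch_to_volume(p, ph, st, psf, sampling = "psf",
                                  steps = c(0.5, 0.25, 0.1))
  expect_true(res$converged)
  expect_lt(max(abs(res$transform$rotation)), 1)
  expect_lt(max(abs(res$transform$translation)), 1)
})
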