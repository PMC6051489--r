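test_that("square patches tile with the requested stride and coverage", {
  sl <- matrix(rnorm(32 * 32), 32, 32)
  masks <- extract_square_patches(sl, a = 32, omega = 16)
  expect_length(masks, 4)  # 2 x 2 lattice positions, clipped to the image
  cover <- matrix(0, 32, 32)
  for (m in masks) cover[m + 1] <- cover[m + 1] + 1
  expect_equal(cover[20, 20], 4)  # interior pixel in ceil(a/omega)^2 patches
  expect_true(all(cover >= 1))
  # stride = size degenerates to one whole-slice patch
  one <- extract_square_patches(sl, a = 32, omega = 32)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]), 32 * 32)
  expect_error(extract_square_patches(sl, a = 8, omega = 9), "omega")
  expect_error(extract_square_patches(sl, a = 2, omega = 1), "at least 4")
})

test_that("partition tiling reassembles the slice exactly", {
  sl <- matrix(rnorm(40 * 24), 40, 24)
  masks <- extract_square_patches(sl, a = 8, omega = 8)
  out <- matrix(NA_real_, 40, 24)
  for (m in masks) out[m + 1] <- sl[m + 1]
  expect_identical(out, sl)
  sizes <- vapply(masks, nrow, numeric(1))
  expect_equal(sum(sizes), 40 * 24)
})

test_that("SLIC labels partition the slice and respect intensity", {
  # constant image: spatial term dominates -> near-Voronoi cells of the grid
  const <- matrix(5, 40, 40)
  labs <- extract_superpixels(const, superpixel_params(a = 10,
                                                       compactness = 1))
  expect_true(all(labs >= 1))
  expect_equal(length(unique(as.vector(labs))), 16)
  sizes <- table(labs)
  # near-Voronoi cells of the seed grid (ties on cell borders may shift
  # a boundary row between neighbours)
  expect_true(all(sizes >= 60 & sizes <= 140))
  # every seed position keeps its own label
  seed_rc <- as.matrix(expand.grid(c(5, 15, 25, 35), c(5, 15, 25, 35)))
  expect_equal(length(unique(labs[seed_rc + 1])), 16)
  # step image: boundary pixels side with the closer centroid intensity
  img <- matrix(0, 48, 48); img[, 25:48] <- 100
  labs2 <- extract_superpixels(img, superpixel_params(a = 12))
  left_labels <- unique(as.vector(labs2[, 1:24]))
  right_labels <- unique(as.vector(labs2[, 25:48]))
  expect_length(intersect(left_labels, right_labels), 0)
  expect_error(extract_superpixels(matrix(NaN, 20, 20),
                                   superpixel_params(a = 8)), "finite")
})

test_that("SLIC is invariant to affine intensity rescaling with t rescaled", {
  set.seed(11)
  img <- matrix(rnorm(40 * 40), 40, 40)
  l1 <- extract_superpixels(img, superpixel_params(a = 10, compactness = 0.5))
  l2 <- extract_superpixels(3 * img + 17,
                            superpixel_params(a = 10, compactness = 1.5))
  expect_identical(l1, l2)
})

test_that("superpixel dilation grows masks monotonically", {
  img <- matrix(0, 8, 8); img[, 5:8] <- 100
  labs <- extract_superpixels(img, superpixel_params(a = 4, compactness = 10))
  m0 <- dilate_superpixels(labs, 0)
  cover0 <- matrix(0, 8, 8)
  for (m in m0) cover0[m + 1] <- cover0[m + 1] + 1
  expect_true(all(cover0 == 1))  # gamma = 0: untouched partition
  sizes <- c(0, 1, 2, 4)
  tot <- vapply(sizes, function(g)
    sum(vapply(dilate_superpixels(labs, g), nrow, numeric(1))), numeric(1))
  expect_true(all(diff(tot) >= 0))
  expect_gt(tot[2], tot[1])
  expect_lte(max(tot), length(unique(as.vector(labs))) * 64)
  # gamma = 1 on a half/half split: only the 1-px boundary band doubles
  half <- matrix(c(rep(1L, 32), rep(2L, 32)), 8, 8)
  md <- dilate_superpixels(half, 1)
  cover <- matrix(0, 8, 8)
  for (m in md) cover[m + 1] <- cover[m + 1] + 1
  expect_true(all(cover[, c(1:3, 6:8)] == 1))
  expect_true(all(cover[, 4:5] == 2))
})

test_that("multiscale schedule follows the geometric progression", {
  s <- multiscale_schedule(16, 1.5, 4, 2)
  expect_equal(s$a, c(16L, 24L, 36L, 54L))
  expect_equal(s$iterations, rep(2L, 4))
  flat <- multiscale_schedule(16, 1, 5)
  expect_true(all(flat$a == 16L))
  expect_error(multiscale_schedule(2), "a0")
  expect_error(multiscale_schedule(16, 0.5), "factor")
})

test_that("patch construction validates and low-information flags work", {
  expect_error(new_patch(1, 0, matrix(numeric(0), ncol = 2), numeric(0)),
               "non-empty")
  expect_error(new_patch(1, 0, cbind(0, 0), NaN), "finite")
  st <- stack96()
  cfg <- pvr_config("square", patch_size = 32L, stride = 16L)
  patches <- pvr:::extract_all_patches(list(st), cfg, 32L, 0L)
  patches <- pvr:::flag_low_variance(patches, list(st))
  reg <- vapply(patches, `[[`, logical(1), "registrable")
  fgfrac <- vapply(patches, function(p) mean(p$y > 50), numeric(1))
  # background-dominated patches must not be registrable
  expect_true(all(!reg[fgfrac < 0.05]))
  expect_true(any(reg))
})
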