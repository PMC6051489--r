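test_that("posterior formula behaves at its analytic extremes", {
  st <- em_state(sigma2 = 4, c = 1, m = 0.05)
  fit <- em_update(c(-5, 0, 5, 20), st, max_iter = 1)
  expect_true(all(fit$p == 1))  # c = 1: everything is an inlier
  st2 <- em_state(sigma2 = 4, c = 0.5, m = 0.05)
  e <- c(-6, -2, 0, 1, 3, 9)
  fit2 <- em_update(e, st2, max_iter = 1)
  expect_equal(which.max(fit2$p), which(e == 0))  # Gaussian peak at zero
  # posteriors decrease monotonically with |e| for a fixed state
  ord <- order(abs(e))
  expect_true(all(diff(fit2$p[ord]) <= 1e-12))
})

test_that("the mixture is recovered on seeded Gaussian+uniform residuals", {
  for (s in 1:10) {
    set.seed(s)
    lab <- runif(10000) < 0.9
    e <- ifelse(lab, rnorm(10000, 0, 1), runif(10000, -20, 20))
    fit <- em_update(e)
    expect_lt(abs(fit$state$c - 0.9), 0.05)
    expect_gt(fit$state$c, 0.85)
    expect_lt(fit$state$c, 0.95)
    expect_lt(mean(fit$p[!lab]), 0.2)
    expect_true(all(diff(fit$loglik) > -1e-8))  # EM ascent
  }
})

test_that("degenerate residuals yield all-inlier posteriors with a flag", {
  fit <- em_update(rep(2.5, 10))
  expect_true(all(fit$p == 1))
  expect_true(fit$state$degenerate)
})

test_that("patch posterior is the root mean square of p", {
  expect_equal(patch_posterior(rep(1, 7)), 1)
  expect_equal(patch_posterior(rep(0, 4)), 0)
  expect_equal(patch_posterior(c(1, 0, 0, 0)), 0.5)
  expect_error(patch_posterior(numeric(0)), "empty")
})

test_that("patch classification follows the threshold policy", {
  mk <- function(ph) {
    p <- new_patch(1, 0, cbind(0:3, 0L), rep(1, 4))
    p$p_hat <- ph
    p
  }
  ps <- classify_patches(list(mk(0.9), mk(0.4), mk(0.5)))
  expect_equal(vapply(ps, `[[`, logical(1), "included"),
               c(TRUE, FALSE, TRUE))
  none <- classify_patches(list(mk(0.9), mk(0.01)), threshold = 0)
  expect_true(all(vapply(none, `[[`, logical(1), "included")))
})

test_that("an injected noise patch is excluded within two EM rounds", {
  pr <- sr_problem()
  set.seed(13)
  # 100 consistent patches (exact observations) + 1 pure-noise patch
  pix <- as.matrix(expand.grid(0:11, 0:11))
  patches <- list()
  for (i in 1:100) {
    k <- (i %% 4) + 1L
    p <- new_patch(1, k, pix, rep(0, nrow(pix)),
                   rigid_transform(c(0, 0, 0), c(0, 0, 0)))
    p$y <- as.numeric(simulate_patch(pr$vol, p, pr$st, pr$psf)) +
      rnorm(nrow(pix), 0, 1)
    patches[[i]] <- p
  }
  noise <- patches[[1]]
  noise$y <- runif(nrow(pix), 0, 200)
  patches[[101]] <- noise
  cache <- pvr:::sr_prepare(patches, list(pr$st), pr$vol, pr$psf)
  x <- as.numeric(pr$vol$voxels)
  st <- NULL
  for (round in 1:2) {
    em <- pvr:::em_round(patches, cache, x, st, max_iter = 20L)
    patches <- em$patches
    st <- em$state
  }
  incl <- vapply(patches, `[[`, logical(1), "included")
  expect_false(incl[101])
  expect_true(all(incl[1:100]))
  # zero-residual patches are never excluded
  expect_true(all(vapply(patches[1:100], `[[`, numeric(1), "p_hat") > 0.5))
})

test_that("the rigidity map is a convex posterior projection", {
  pr <- sr_problem()
  patches <- lapply(pr$patches, function(p) { p$p[] <- 1; p$p_hat <- 1; p })
  map <- build_rigidity_map(patches, pr$cache, pr$vol)
  covered <- map$voxels > 0
  expect_true(all(map$voxels >= 0 & map$voxels <= 1))
  expect_true(all(abs(map$voxels[covered] - 1) < 1e-9))
  # un-touched voxels stay exactly zero
  den <- numeric(prod(dim(pr$vol$voxels)))
  for (i in seq_along(patches))
    den <- pvr:::cpp_scatter_csr(rep(1, length(patches[[i]]$p)),
                                 pr$cache[[i]]$ptr, pr$cache[[i]]$idx,
                                 pr$cache[[i]]$w, den)
  expect_true(all(map$voxels[array(den == 0, dim(map$voxels))] == 0))
  # halving the posteriors halves the map on covered voxels
  half <- lapply(patches, function(p) { p$p[] <- 0.5; p })
  map2 <- build_rigidity_map(half, pr$cache, pr$vol)
  expect_equal(map2$voxels[covered], 0.5 * map$voxels[covered],
               tolerance = 1e-9)
})

test_that("em_state validates its invariants", {
  expect_error(em_state(0, 0.5, 1), "sigma2")
  expect_error(em_state(1, 1.5, 1), "c must")
  expect_error(em_state(1, 0.5, 0), "m must")
})
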