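test_that("phi is the stated edge-preserving penalty", {
  expect_equal(phi(0), 0)
  expect_equal(phi(1), 2 * sqrt(2) - 2)
  expect_equal(phi(-3), phi(3))
  expect_lt(abs(phi(1e6) / 1e6 - 2), 1e-5)  # asymptotically linear, slope 2
})

test_that("lambda halves every iteration from 0.8 delta^2", {
  expect_equal(lambda_schedule(150, 0), 0.8 * 150^2)
  expect_equal(lambda_schedule(150, 1), 0.8 * 150^2 / 2)
  lam <- vapply(0:8, function(k) lambda_schedule(150, k), numeric(1))
  expect_true(all(diff(lam) < 0))
  expect_error(lambda_schedule(0), "delta")
})

test_that("patch simulation matches a brute-force oracle", {
  pr <- sr_problem()
  p <- pr$patches[[2]]
  sim <- simulate_patch(pr$vol, p, pr$st, pr$psf)
  # independent oracle: full triple loop over the HR grid per pixel
  pw <- pvr:::patch_pixel_world(p, pr$st)
  axes <- pvr:::patch_axes(p, pr$st)
  d <- dim(pr$vol$voxels)
  pick <- seq(1, nrow(pw), by = 7)
  for (j in pick) {
    grid_idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1),
                                      0:(d[3] - 1)))
    q <- voxel_to_world(pr$vol, grid_idx)
    offs <- t(t(axes) %*% (t(q) - pw[j, ]))
    w <- psf_weight(offs, pr$psf)
    expected <- if (sum(w) > 0)
      sum(w * pr$vol$voxels[grid_idx + 1]) / sum(w) else 0
    expect_equal(sim[j], expected, tolerance = 1e-9)
  }
  # constant volume simulates to the constant (convex weights)
  volc <- pr$vol; volc$voxels[] <- 42
  simc <- simulate_patch(volc, p, pr$st, pr$psf)
  expect_true(all(abs(simc[attr(simc, "covered")] - 42) < 1e-9))
})

test_that("a near-delta PSF reduces simulation to nearest-voxel sampling", {
  pr <- sr_problem()
  p <- pr$patches[[1]]  # identity transform
  tiny <- psf_model(c(0.05, 0.05), 0.05, support_radius = 0.6)
  sim <- simulate_patch(pr$vol, p, pr$st, tiny)
  cov <- attr(sim, "covered")
  vx <- round(world_to_voxel(pr$vol, pvr:::patch_pixel_world(p, pr$st)))
  nearest <- pr$vol$voxels[vx + 1]
  expect_equal(sim[cov], nearest[cov], tolerance = 1e-6)
})

test_that("the data-term gradient matches finite differences", {
  pr <- sr_problem()
  x <- as.numeric(pr$vol$voxels)
  lambda <- 10; delta <- 20
  dims <- dim(pr$vol$voxels)
  obj <- pvr:::sr_objective(x, pr$patches, pr$cache, lambda, delta, dims)
  resid <- numeric(length(x))
  for (i in seq_along(pr$patches)) {
    sim <- pvr:::cpp_sim_csr(x, pr$cache[[i]]$ptr, pr$cache[[i]]$idx,
                             pr$cache[[i]]$w)
    w <- pr$patches[[i]]$p_hat * pr$patches[[i]]$p
    resid <- pvr:::cpp_scatter_csr(w * (pr$patches[[i]]$y - sim),
                                   pr$cache[[i]]$ptr, pr$cache[[i]]$idx,
                                   pr$cache[[i]]$w, resid)
  }
  grad <- -2 * resid + lambda * obj$reg_grad
  set.seed(1)
  for (v in sample(length(x), 12)) {
    h <- 1e-3
    xp <- x; xp[v] <- xp[v] + h
    xm <- x; xm[v] <- xm[v] - h
    fd <- (pvr:::sr_objective(xp, pr$patches, pr$cache, lambda, delta,
                              dims)$total -
           pvr:::sr_objective(xm, pr$patches, pr$cache, lambda, delta,
                              dims)$total) / (2 * h)
    expect_lt(abs(fd - grad[v]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("sr steps decrease the objective monotonically", {
  pr <- sr_problem()
  state <- sr_state(pr$vol, lambda = 10, delta = 20)
  objs <- numeric(0)
  for (i in 1:10) {
    state <- sr_step(state, pr$patches, pr$cache)
    expect_true(attr(state, "accepted"))
    objs <- c(objs, attr(state, "objective"))
  }
  expect_true(all(diff(objs) < 0))
})

test_that("consistent observations are a fixed point and errors contract", {
  pr <- sr_problem()
  # exact observations of the current volume with full confidence
  patches <- lapply(pr$patches, function(p) {
    p$y <- as.numeric(simulate_patch(pr$vol, p, pr$st, pr$psf))
    p$p[] <- 1; p$p_hat <- 1
    p
  })
  cache <- pvr:::sr_prepare(patches, list(pr$st), pr$vol, pr$psf)
  st0 <- sr_state(pr$vol, lambda = 1e-9, delta = 150)
  st1 <- sr_step(st0, patches, cache)
  # the data fit is a fixed point: simulations still reproduce y exactly
  # (voxels no patch observes may still relax under the regularizer)
  sims1 <- pvr:::simulate_all(as.numeric(st1$volume$voxels), patches, cache)
  res1 <- unlist(lapply(seq_along(patches), function(i)
    (patches[[i]]$y - sims1[[i]])[cache[[i]]$covered]))
  expect_lt(max(abs(res1)), 1e-6)
  # observed voxels themselves stay put
  conf <- array(st1$confidence, dim(pr$vol$voxels))
  expect_lt(max(abs((st1$volume$voxels - pr$vol$voxels)[conf > 0.1])), 1e-6)
  # from a perturbed start the simulation residual contracts toward zero
  pert <- pr$vol
  set.seed(2)
  pert$voxels <- pert$voxels + array(rnorm(length(pert$voxels), 0, 5),
                                     dim(pert$voxels))
  res_norm <- function(vol) {
    sims <- pvr:::simulate_all(as.numeric(vol$voxels), patches, cache)
    sqrt(mean(unlist(lapply(seq_along(patches), function(i)
      ((patches[[i]]$y - sims[[i]])[cache[[i]]$covered])^2))))
  }
  st <- sr_state(pert, lambda = 1e-9, delta = 150)
  r0 <- res_norm(st$volume)
  st <- pvr:::sr_solve(st, patches, cache, n_iter = 25)
  expect_lt(res_norm(st$volume), 0.05 * r0)
})

test_that("a heavily regularized volume flattens", {
  pr <- sr_problem()
  # no data: zero posterior weight everywhere
  patches <- lapply(pr$patches, function(p) { p$p[] <- 0; p$p_hat <- 0; p })
  state <- sr_state(pr$vol, lambda = 1e6, delta = 5)
  v0 <- var(as.numeric(state$volume$voxels))
  for (i in 1:15) state <- sr_step(state, patches, pr$cache, step0 = 1)
  expect_lt(var(as.numeric(state$volume$voxels)), 0.2 * v0)
})

test_that("zero patch posterior removes a patch's influence exactly", {
  pr <- sr_problem()
  run <- function(patches) {
    state <- sr_state(pr$vol, lambda = 10, delta = 150)
    cache <- pvr:::sr_prepare(patches, list(pr$st), pr$vol, pr$psf)
    pvr:::sr_solve(state, patches, cache, n_iter = 3)$volume$voxels
  }
  zeroed <- pr$patches
  zeroed[[2]]$y <- zeroed[[2]]$y + 1000  # would change the fit if counted
  zeroed[[2]]$p_hat <- 0
  zeroed[[2]]$included <- FALSE
  removed <- pr$patches[-2]
  expect_identical(run(zeroed), run(removed))
})

test_that("sr_state validates its inputs", {
  pr <- sr_problem()
  expect_error(sr_state(pr$vol, lambda = 0), "lambda")
  expect_error(sr_state(pr$vol, lambda = 1, delta = -1), "delta")
  bad <- pr$vol; bad$voxels[1] <- NaN
  expect_error(sr_state(bad, lambda = 1), "finite")
})
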