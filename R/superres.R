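#' Edge-preserving penalty function
#'
#' `phi(t) = 2 sqrt(1 + t^2) - 2`: even, smooth, zero at zero, and
#' asymptotically linear, so large intensity gradients (edges) are
#' penalized linearly rather than quadratically.
#'
#' @param t numeric vector (dimensionless gradient ratio).
#' @export
phi <- function(t) 2 * sqrt(1 + t^2) - 2

#' Regularization weight schedule
#'
#' The regularization weight starts at `lambda0_factor * delta^2`
#' (default 0.8) and is halved after every outer iteration.
#'
#' @param delta edge threshold (intensity-gradient units).
#' @param iteration 0-based outer iteration count.
#' @param lambda0_factor multiplier of `delta^2` at iteration 0.
#' @export
lambda_schedule <- function(delta, iteration = 0, lambda0_factor = 0.8) {
  if (delta <= 0) stop("delta must be positive")
  lambda0_factor * delta^2 / 2^iteration
}

# slice-frame axes of a patch under its current transform, as unit
# columns in the reconstruction frame
patch_axes <- function(patch, stack) {
  euler_to_rotation(patch$transform$rotation) %*% stack$direction
}

# world positions of the patch's pixel centres in the reconstruction frame
patch_pixel_world <- function(patch, stack) {
  apply_transform(patch$transform,
                  voxel_to_world(stack, cbind(patch$pix, patch$slice_index)))
}

#' Simulate a patch from the reconstruction through the PSF
#'
#' Each pixel's simulated value is the normalized PSF-weighted sum of the
#' HR voxels inside the pixel's transformed footprint; pixels whose
#' footprint carries no weight (out of field) are flagged.
#'
#' @param volume Current reconstruction ([pvr_volume()]).
#' @param patch A `pvr_patch` with its transform set.
#' @param stack The stack the patch belongs to.
#' @param psf A [psf_model()].
#' @return Numeric vector of simulated intensities over the patch mask;
#'   attribute `covered` flags pixels with nonzero footprint.
#' @export
simulate_patch <- function(volume, patch, stack, psf) {
  fp <- psf_footprint(patch_pixel_world(patch, stack),
                      patch_axes(patch, stack), volume, psf)
  out <- cpp_sim_csr(as.numeric(volume$voxels), fp$ptr, fp$idx, fp$w)
  attr(out, "covered") <- diff(fp$ptr) > 0
  out
}

# Precompute CSR footprints for all patches (transforms frozen between
# registration passes). `prune` drops weights below prune * max(weight)
# per pixel before renormalization — an SR discretization control.
sr_prepare <- function(patches, stacks, grid, psf, prune = 0) {
  lapply(patches, function(p) {
    stack <- stacks[[p$stack_id]]
    fp <- psf_footprint(patch_pixel_world(p, stack), patch_axes(p, stack),
                        grid, psf, prune = prune)
    fp$covered <- diff(fp$ptr) > 0
    fp
  })
}

# Scatter per-pixel values of every included patch into the HR grid.
# `values_fn(patch, i)` returns the vector to scatter for patch i.
scatter_all <- function(patches, cache, nvox, values_fn) {
  acc <- numeric(nvox)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!p$included) next
    acc <- cpp_scatter_csr(values_fn(p, i), cache[[i]]$ptr, cache[[i]]$idx,
                           cache[[i]]$w, acc)
  }
  acc
}

simulate_all <- function(x, patches, cache) {
  lapply(seq_along(patches), function(i)
    cpp_sim_csr(x, cache[[i]]$ptr, cache[[i]]$idx, cache[[i]]$w))
}

# Confidence-weighted PSF scatter of the observed intensities: the
# initial estimate of X. Uncovered voxels take the foreground median.
sr_init <- function(patches, cache, grid) {
  nvox <- prod(vol_dim(grid))
  num <- scatter_all(patches, cache, nvox, function(p, i) p$p_hat * p$p * p$y)
  den <- scatter_all(patches, cache, nvox, function(p, i) p$p_hat * p$p)
  x <- num
  covered <- den > 1e-12
  x[covered] <- num[covered] / den[covered]
  ys <- unlist(lapply(patches, `[[`, "y"), use.names = FALSE)
  fill <- median(ys[ys > 0.05 * quantile(ys, 0.99, names = FALSE)])
  if (!is.finite(fill)) fill <- median(ys)
  x[!covered] <- fill
  out <- grid
  out$voxels <- array(x, vol_dim(grid))
  attr(out, "confidence") <- array(den, vol_dim(grid))
  out
}

#' Super-resolution state
#'
#' Bundles the current reconstruction, its per-voxel accumulated
#' confidence, and the regularization parameters for [sr_step()].
#'
#' @param volume Current reconstruction ([pvr_volume()]).
#' @param confidence per-voxel accumulated posterior-weighted PSF weight.
#' @param lambda current regularization weight (> 0).
#' @param delta edge threshold in intensity-gradient units.
#' @param iteration inner-iteration counter.
#' @export
sr_state <- function(volume, confidence = NULL, lambda = 1, delta = 150,
                     iteration = 0L) {
  if (lambda <= 0) stop("lambda must be positive")
  if (delta <= 0) stop("delta must be positive")
  if (any(!is.finite(volume$voxels))) stop("volume must be finite")
  structure(list(volume = volume, confidence = confidence, lambda = lambda,
                 delta = delta, iteration = as.integer(iteration)),
            class = "pvr_sr_state")
}

# objective = sum_s p_hat sum_j p_j (y - y*)^2 + lambda * R(x)
sr_objective <- function(x, patches, cache, lambda, delta, dim) {
  data <- 0
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!p$included) next
    sim <- cpp_sim_csr(x, cache[[i]]$ptr, cache[[i]]$idx, cache[[i]]$w)
    r <- (p$y - sim)[cache[[i]]$covered]
    pj <- p$p[cache[[i]]$covered]
    data <- data + p$p_hat * sum(pj * r * r)
  }
  reg <- cpp_reg26(x, dim, delta)
  list(total = data + lambda * reg$value, data = data,
       reg = reg$value, reg_grad = reg$grad)
}

#' One gradient-descent super-resolution update
#'
#' Performs a single preconditioned gradient step on the objective
#' `sum_s p_hat_s sum_j p_j (y_j - y*_j)^2 + lambda R(X)` with the
#' 26-neighbourhood edge-preserving regularizer `R`. Residuals are
#' scattered back to HR voxels with the same normalized PSF weights used
#' in simulation (the adjoint of the forward operator), weighted by the
#' EM posteriors. The step size is found by backtracking line search
#' (halving from `step0`); a step that cannot decrease the objective is
#' rejected and flagged. Voxels with zero confidence receive no data-term
#' update.
#'
#' @param state An [sr_state()].
#' @param patches list of `pvr_patch` with posteriors set.
#' @param cache footprint cache from `sr_prepare` (rebuilt automatically
#'   when `NULL`).
#' @param stacks,psf needed only when `cache` is `NULL`.
#' @param step0 initial relative step size.
#' @param max_backtracks backtracking halvings before rejecting.
#' @return Updated [sr_state()]; attribute `accepted` reports whether the
#'   step was taken, attribute `objective` the objective after the step.
#' @export
sr_step <- function(state, patches, cache = NULL, stacks = NULL, psf = NULL,
                    step0 = 1, max_backtracks = 8L) {
  grid <- state$volume
  dim <- vol_dim(grid)
  nvox <- prod(dim)
  if (is.null(cache)) cache <- sr_prepare(patches, stacks, grid, psf)
  x <- as.numeric(grid$voxels)

  resid <- numeric(nvox)
  conf <- numeric(nvox)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!p$included) next
    sim <- cpp_sim_csr(x, cache[[i]]$ptr, cache[[i]]$idx, cache[[i]]$w)
    w <- p$p_hat * p$p
    resid <- cpp_scatter_csr(w * (p$y - sim), cache[[i]]$ptr, cache[[i]]$idx,
                             cache[[i]]$w, resid)
    conf <- cpp_scatter_csr(w, cache[[i]]$ptr, cache[[i]]$idx, cache[[i]]$w,
                            conf)
  }
  obj <- sr_objective(x, patches, cache, state$lambda, state$delta, dim)
  grad <- -2 * resid + state$lambda * obj$reg_grad
  # Jacobi-style preconditioner: data curvature 2*conf, regularizer
  # curvature bounded by phi''(0) = 2 summed over the neighbourhood
  dlen2 <- c(rep(1, 6), rep(2, 12), rep(3, 8))
  reg_curv <- sum(4 / (state$delta^2 * dlen2)) / 26
  precond <- 2 * conf + state$lambda * reg_curv + 1e-12
  dir <- grad / precond

  alpha <- step0
  accepted <- FALSE
  for (bt in 0:max_backtracks) {
    xc <- x - alpha * dir
    obj_c <- sr_objective(xc, patches, cache, state$lambda, state$delta, dim)
    if (obj_c$total < obj$total) {
      accepted <- TRUE
      break
    }
    alpha <- alpha / 2
  }
  out <- state
  if (accepted) {
    out$volume$voxels <- array(xc, dim)
    out$iteration <- state$iteration + 1L
  }
  out$confidence <- array(conf, dim)
  attr(out, "accepted") <- accepted
  attr(out, "objective") <- if (accepted) obj_c$total else obj$total
  attr(out, "data_term") <- if (accepted) obj_c$data else obj$data
  out
}

# Run `n_iter` SR steps with fixed transforms/posteriors; returns the
# state plus the per-iteration objective trace.
sr_solve <- function(state, patches, cache, n_iter = 7L, step0 = 1) {
  trace <- numeric(0)
  for (it in seq_len(n_iter)) {
    state <- sr_step(state, patches, cache, step0 = step0)
    trace <- c(trace, attr(state, "objective"))
    if (!attr(state, "accepted")) break
  }
  attr(state, "trace") <- trace
  state
}
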