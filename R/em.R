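#' EM mixture state for inlier/outlier classification
#'
#' Residuals `e = y - y*` are modelled as a mixture of a zero-mean
#' Gaussian (inliers, variance `sigma2`, proportion `c`) and a uniform
#' distribution over the observed error range (outliers, density
#' `m = 1 / (max(e) - min(e))`).
#'
#' @param sigma2 inlier variance (intensity^2 units), > 0.
#' @param c inlier mixing proportion in `[0, 1]`.
#' @param m uniform outlier density, > 0.
#' @return An object of class `pvr_em_state`.
#' @export
em_state <- function(sigma2, c, m) {
  if (!(sigma2 > 0)) stop("sigma2 must be positive")
  if (c < 0 || c > 1) stop("c must lie in [0, 1]")
  if (!(m > 0)) stop("m must be positive")
  structure(list(sigma2 = sigma2, c = c, m = m, degenerate = FALSE),
            class = "pvr_em_state")
}

#' EM update of the inlier/outlier mixture
#'
#' E-step: posterior `p = G_sigma(e) c / (G_sigma(e) c + m (1 - c))` with
#' `G_sigma` a zero-mean Gaussian density. M-step: `sigma2` becomes the
#' posterior-weighted mean of `e^2` and `c` the mean posterior; the
#' uniform density `m` comes from the error range. Iterates until the
#' change in `c` drops below `tol` or `max_iter` is reached. The
#' log-likelihood is non-decreasing across iterations.
#'
#' @param errors numeric vector of residuals (>= 2 distinct values unless
#'   degenerate).
#' @param state optional initial [em_state()]; defaults to `c = 0.9`,
#'   `sigma2 = var(errors)`.
#' @param max_iter,tol convergence controls.
#' @return A list with `p` (posteriors), `state` (updated [em_state()]),
#'   `loglik` (trace), and `iterations`.
#' @export
em_update <- function(errors, state = NULL, max_iter = 20L, tol = 1e-4) {
  e <- as.numeric(errors)
  if (length(e) < 1L) stop("no residuals")
  rng <- max(e) - min(e)
  if (rng <= 0) {
    # no outlier evidence whatsoever
    st <- em_state(max(var(c(e, e[1] + 1e-12)), 1e-12), 1, 1)
    st$degenerate <- TRUE
    return(list(p = rep(1, length(e)), state = st, loglik = numeric(0),
                iterations = 0L))
  }
  m <- 1 / rng
  if (is.null(state)) {
    sigma2 <- max(var(e), 1e-12)
    cc <- 0.9
  } else {
    sigma2 <- state$sigma2
    cc <- state$c
  }
  loglik <- numeric(0)
  iterations <- 0L
  p <- rep(1, length(e))
  for (it in seq_len(max_iter)) {
    g <- dnorm(e, 0, sqrt(sigma2))
    denom <- g * cc + m * (1 - cc)
    loglik <- c(loglik, sum(log(pmax(denom, 1e-300))))
    # c = 1: every observation is an inlier by definition (0/0 -> 1)
    p <- if (cc >= 1) rep(1, length(e))
         else (g * cc) / pmax(denom, 1e-300)
    cc_new <- mean(p)
    sigma2 <- max(sum(p * e^2) / max(sum(p), 1e-12), 1e-12)
    iterations <- it
    conv <- abs(cc_new - cc) < tol
    cc <- cc_new
    if (conv) break
  }
  list(p = p, state = em_state(sigma2, cc, m), loglik = loglik,
       iterations = iterations)
}

#' Patch posterior from per-pixel posteriors
#'
#' Root-mean-square aggregation: `p_hat = sqrt(sum(p^2) / N)`.
#'
#' @param p_values per-pixel inlier posteriors of one patch.
#' @export
patch_posterior <- function(p_values) {
  if (length(p_values) == 0L) stop("empty patch")
  sqrt(sum(p_values^2) / length(p_values))
}

#' Classify patches as included or excluded
#'
#' A patch is excluded when its outlier responsibility exceeds its inlier
#' responsibility, i.e. when `p_hat < threshold` (default 0.5). Excluded
#' patches contribute zero weight to the super-resolution but keep being
#' re-registered and may re-enter later.
#'
#' @param patches list of `pvr_patch` with `p_hat` set.
#' @param threshold exclusion threshold on `p_hat`; 0 excludes nothing.
#' @return The patches with their `included` flags updated.
#' @export
classify_patches <- function(patches, threshold = 0.5) {
  for (i in seq_along(patches))
    patches[[i]]$included <- patches[[i]]$p_hat >= threshold
  patches
}

# One EM round over all included patches: simulate, collect residuals,
# fit the mixture, write posteriors back. The mixture state is carried
# across reconstruction iterations and refreshed with `max_iter` EM
# updates per round (one by default): iterating the noise-free mixture to
# convergence inside a round collapses sigma onto the flat-region
# residual peak and rejects every edge.
em_round <- function(patches, cache, x, state = NULL, threshold = 0.5,
                     max_iter = 1L) {
  sims <- simulate_all(x, patches, cache)
  res_list <- vector("list", length(patches))
  use <- logical(length(patches))
  for (i in seq_along(patches)) {
    cov <- cache[[i]]$covered
    if (!patches[[i]]$included || !any(cov)) next
    use[i] <- TRUE
    res_list[[i]] <- (patches[[i]]$y - sims[[i]])[cov]
  }
  all_e <- unlist(res_list[use], use.names = FALSE)
  if (length(all_e) < 2L) return(list(patches = patches, state = state))
  fit <- em_update(all_e, state, max_iter = max_iter)
  # write voxel posteriors back patch by patch
  offset <- 0L
  for (i in seq_along(patches)) {
    if (!use[i]) {
      # excluded patches: score them against the fitted mixture so they
      # can re-enter once consistent
      if (!patches[[i]]$included && any(cache[[i]]$covered)) {
        cov <- cache[[i]]$covered
        e <- (patches[[i]]$y - sims[[i]])[cov]
        g <- dnorm(e, 0, sqrt(fit$state$sigma2))
        pp <- (g * fit$state$c) /
          pmax(g * fit$state$c + fit$state$m * (1 - fit$state$c), 1e-300)
        patches[[i]]$p[] <- 0
        patches[[i]]$p[cov] <- pp
        patches[[i]]$p_hat <- patch_posterior(pp)
      }
      next
    }
    n <- length(res_list[[i]])
    pp <- fit$p[(offset + 1L):(offset + n)]
    offset <- offset + n
    cov <- cache[[i]]$covered
    patches[[i]]$p[] <- 0
    patches[[i]]$p[cov] <- pp
    patches[[i]]$p_hat <- patch_posterior(pp)
  }
  patches <- classify_patches(patches, threshold)
  list(patches = patches, state = fit$state)
}

#' Build the rigidity / uncertainty map
#'
#' Projects the combined posteriors `p * p_hat` of every contributing
#' patch pixel into the HR grid with the same normalized PSF weights used
#' for reconstruction. Values near 1 mark regions whose motion was
#' consistent with the rigid patch model; voxels no patch touches are 0.
#'
#' @param patches list of `pvr_patch` with posteriors.
#' @param cache footprint cache from `sr_prepare` (or `NULL` to build it).
#' @param grid HR-grid [pvr_volume()] providing the geometry.
#' @param stacks,psf needed only when `cache` is `NULL`.
#' @return A [pvr_volume()] with values in `[0, 1]`.
#' @export
build_rigidity_map <- function(patches, cache = NULL, grid, stacks = NULL,
                               psf = NULL) {
  if (is.null(cache)) cache <- sr_prepare(patches, stacks, grid, psf)
  nvox <- prod(vol_dim(grid))
  num <- numeric(nvox)
  den <- numeric(nvox)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    num <- cpp_scatter_csr(p$p * p$p_hat, cache[[i]]$ptr, cache[[i]]$idx,
                           cache[[i]]$w, num)
    den <- cpp_scatter_csr(rep(1, length(p$p)), cache[[i]]$ptr,
                           cache[[i]]$idx, cache[[i]]$w, den)
  }
  vals <- numeric(nvox)
  cov <- den > 1e-12
  vals[cov] <- pmin(pmax(num[cov] / den[cov], 0), 1)
  out <- grid
  out$voxels <- array(vals, vol_dim(grid))
  out
}
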