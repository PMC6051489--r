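#' Select the template stack with fewest motion artifacts
#'
#' Scores each stack by the mean normalized cross-correlation between
#' consecutive slices — through-plane inconsistency is a proxy for
#' inter-slice motion — and returns the index of the best-scoring stack.
#' Ties break deterministically to the lowest index.
#'
#' @param stacks list of [pvr_volume()] stacks.
#' @return Integer stack index (1-based).
#' @export
select_template_stack <- function(stacks) {
  if (length(stacks) == 0L) stop("at least one stack is required")
  score <- vapply(stacks, function(s) {
    d <- vol_dim(s)
    if (d[3] < 2L) return(0)
    ncc <- vapply(seq_len(d[3] - 1L), function(k) {
      a <- as.numeric(s$voxels[, , k]); b <- as.numeric(s$voxels[, , k + 1L])
      if (sd(a) == 0 || sd(b) == 0) return(0)
      suppressWarnings(stats::cor(a, b))
    }, numeric(1))
    mean(ncc, na.rm = TRUE)
  }, numeric(1))
  which.max(score)  # which.max takes the first maximum: lowest index
}

# foreground = voxels above 5% of the 99th intensity percentile
foreground_median <- function(volume) {
  v <- as.numeric(volume$voxels)
  thr <- 0.05 * quantile(v, 0.99, names = FALSE)
  fg <- v[v > thr]
  if (length(fg) == 0L) stop("stack has no foreground (all-zero image?)")
  median(fg)
}

#' Global intensity matching against a template stack
#'
#' Each stack is rescaled by a single gain (no offset) so its foreground
#' median equals the template's; the template is returned unchanged.
#'
#' @param stacks list of [pvr_volume()] stacks.
#' @param template_index index of the template stack.
#' @return List of rescaled stacks; gains are attached as attribute
#'   `gains`.
#' @export
match_intensities <- function(stacks, template_index = 1L) {
  stopifnot(template_index >= 1, template_index <= length(stacks))
  ref <- foreground_median(stacks[[template_index]])
  gains <- vapply(stacks, function(s) ref / foreground_median(s), numeric(1))
  out <- lapply(seq_along(stacks), function(i) {
    s <- stacks[[i]]
    s$voxels <- s$voxels * gains[i]
    s
  })
  attr(out, "gains") <- gains
  out
}

## ---- optimizer -----------------------------------------------------------

# Greedy coordinate descent over the 6 rigid parameters, maximizing `f`.
# For each step size, sweep the parameters; on improvement keep walking in
# the same direction. Rotation steps in degrees, translation in mm.
coord_descent_rigid <- function(par, f, steps = c(2, 1, 0.5, 0.25, 0.1),
                                max_sweeps = 6L, active = seq_len(6L),
                                lower = rep(-Inf, 6L), upper = rep(Inf, 6L)) {
  best <- f(par)
  if (!is.finite(best)) return(list(par = par, value = best, evals = 0L))
  evals <- 0L
  for (s in steps) {
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (j in active) {
        for (sgn in c(1, -1)) {
          cand <- par
          cand[j] <- cand[j] + sgn * s
          if (cand[j] < lower[j] || cand[j] > upper[j]) next
          v <- f(cand)
          evals <- evals + 1L
          if (is.finite(v) && v > best + 1e-12) {
            # keep walking while it pays off
            repeat {
              par <- cand
              best <- v
              improved <- TRUE
              cand <- par
              cand[j] <- cand[j] + sgn * s
              if (cand[j] < lower[j] || cand[j] > upper[j]) break
              v <- f(cand)
              evals <- evals + 1L
              if (!is.finite(v) || v <= best + 1e-12) break
            }
            break  # direction found; next parameter
          }
        }
      }
      if (!improved) break
    }
  }
  list(par = par, value = best, evals = evals)
}

registration_result <- function(transform, similarity, converged,
                                iterations_used) {
  structure(list(transform = transform, similarity = similarity,
                 converged = converged, iterations_used = iterations_used),
            class = "pvr_registration")
}

#' @export
print.pvr_registration <- function(x, ...) {
  cat(sprintf("<pvr_registration> CC = %.4f, converged = %s (%d evals)\n",
              x$similarity, x$converged, x$iterations_used))
  print(x$transform)
  invisible(x)
}

# box-blur + stride-2 decimation for the multiresolution pyramid
downsample_volume <- function(volume) {
  d <- vol_dim(volume)
  sm <- array(cpp_box_blur3(as.numeric(volume$voxels), d, 1L, 1L), d)
  ii <- seq(1, d[1], by = 2); jj <- seq(1, d[2], by = 2)
  kk <- seq(1, d[3], by = 2)
  pvr_volume(sm[ii, jj, kk, drop = FALSE], spacing = volume$spacing * 2,
             origin = volume$origin, direction = volume$direction)
}

# CC of moving sampled on the fixed grid under candidate params
cc_volume_pair <- function(moving, fixed, par, center) {
  tr <- rigid_transform(par[1:3], par[4:6], center)
  A <- (solve(voxel_to_world_matrix(moving)) %*%
        solve(as_affine_matrix(tr)) %*%
        voxel_to_world_matrix(fixed))[1:3, , drop = FALSE]
  d <- vol_dim(fixed)
  pts <- rbind(rep(0:(d[1] - 1), times = d[2] * d[3]),
               rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
               rep(0:(d[3] - 1), each = d[1] * d[2]))
  r <- cpp_eval_cc(moving$voxels, vol_dim(moving), A, pts,
                   as.numeric(fixed$voxels))
  if (r[2] < 0.25) return(NA_real_)
  r[1]
}

#' Rigid 3D-3D registration by cross-correlation
#'
#' Multi-resolution (3-level pyramid) derivative-free maximization of the
#' cross-correlation between the fixed volume and the transformed moving
#' volume. The returned transform maps moving-world points to fixed-world
#' points and its similarity is never below that of `init`.
#'
#' @param moving,fixed [pvr_volume()] objects with overlapping fields of
#'   view.
#' @param init Initial [rigid_transform()] (identity about the moving
#'   volume's centre if `NULL`).
#' @param levels Number of pyramid levels.
#' @return A `pvr_registration` result.
#' @export
register_volume_3d <- function(moving, fixed, init = NULL, levels = 3L) {
  d <- vol_dim(moving)
  center <- as.numeric(voxel_to_world(moving, (d - 1) / 2))
  if (is.null(init)) init <- rigid_transform(center = center)
  init <- rebase_center(init, center)
  par <- c(init$rotation, init$translation)

  pyr_m <- list(moving); pyr_f <- list(fixed)
  for (l in seq_len(levels - 1L)) {
    if (min(vol_dim(pyr_m[[l]])) < 12 || min(vol_dim(pyr_f[[l]])) < 12) break
    pyr_m[[l + 1L]] <- downsample_volume(pyr_m[[l]])
    pyr_f[[l + 1L]] <- downsample_volume(pyr_f[[l]])
  }
  evals <- 0L
  v0 <- cc_volume_pair(moving, fixed, par, center)
  for (l in rev(seq_along(pyr_m))) {
    f <- function(p) cc_volume_pair(pyr_m[[l]], pyr_f[[l]], p, center)
    coarsest <- l == length(pyr_m) && length(pyr_m) > 1L
    st <- if (l == 1L) c(0.5, 0.25, 0.1) else if (coarsest)
      c(4, 2, 1) else c(2, 1, 0.5)
    # translation first at the coarsest level: rotations are poorly
    # constrained once fine structure is averaged away
    act <- if (coarsest) 4:6 else seq_len(6L)
    res <- coord_descent_rigid(par, f, steps = st, active = act)
    par <- res$par
    evals <- evals + res$evals
  }
  v1 <- cc_volume_pair(moving, fixed, par, center)
  if (!is.finite(v1) || (is.finite(v0) && v1 < v0)) {
    # no overlap or no improvement: fall back to the initialization
    return(registration_result(init, if (is.finite(v0)) v0 else NA_real_,
                               FALSE, evals))
  }
  registration_result(rigid_transform(par[1:3], par[4:6], center), v1,
                      TRUE, evals)
}

# world positions (stack frame) of a patch's pixel centres
patch_pixel_matrix <- function(patch) {
  rbind(t(patch$pix), patch$slice_index)  # 3 x n voxel indices in the stack
}

# CC between patch intensities and the volume sampled (trilinear) at the
# transformed pixel centres; `pix3` is 3 x n stack-voxel indices.
cc_patch_pose <- function(volume, stack, pix3, y, par, center,
                          min_overlap = 0.5) {
  tr <- rigid_transform(par[1:3], par[4:6], center)
  A <- (solve(voxel_to_world_matrix(volume)) %*% as_affine_matrix(tr) %*%
        voxel_to_world_matrix(stack))[1:3, , drop = FALSE]
  r <- cpp_eval_cc(volume$voxels, vol_dim(volume), A, pix3, y)
  if (r[2] < min_overlap) return(NA_real_)
  r[1]
}

# CC evaluated through the full PSF forward model (simulated patch)
cc_patch_pose_psf <- function(volume, stack, pix3, y, par, center, psf,
                              min_overlap = 0.5) {
  tr <- rigid_transform(par[1:3], par[4:6], center)
  pw <- apply_transform(tr, voxel_to_world(stack, t(pix3)))
  axes <- euler_to_rotation(tr$rotation) %*% stack$direction
  fp <- psf_footprint(pw, axes, volume, psf)
  sim <- cpp_sim_csr(volume$voxels, fp$ptr, fp$idx, fp$w)
  covered <- diff(fp$ptr) > 0
  if (mean(covered) < min_overlap) return(NA_real_)
  a <- sim[covered]; b <- y[covered]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Register a 2D patch to the reconstruction volume
#'
#' Maximizes the cross-correlation between the patch intensities and the
#' volume evaluated at the rigidly transformed pixel positions,
#' warm-started from the patch's current transform. The rotation centre
#' is the patch centroid. `sampling = "linear"` (default) samples the
#' volume trilinearly at the pixel centres; `sampling = "psf"` simulates
#' the patch through the full PSF forward model at every candidate pose.
#' The returned similarity is never below the warm start's.
#'
#' Two search profiles are provided. `"fast"` runs bounded coordinate
#' descent over a smoothing pyramid and suits the warm-started refinement
#' inside the reconstruction loop, where inter-iteration pose changes are
#' small. `"robust"` precedes the local polish with a multi-start
#' Nelder-Mead simplex search over out-of-plane rotation offsets — a flat
#' 2D patch has its weakest identifiability in the out-of-plane angles —
#' and attains the module's stated capture range of about 5 degrees /
#' 5 mm at roughly ten times the cost.
#'
#' @param patch A `pvr_patch`.
#' @param volume Current reconstruction ([pvr_volume()]).
#' @param stack The stack the patch was extracted from (for its geometry).
#' @param psf A [psf_model()] (used when `sampling = "psf"`).
#' @param sampling `"linear"` or `"psf"`.
#' @param steps step schedule (degrees / mm) for the coordinate search at
#'   the finest level.
#' @param min_overlap minimum in-field pixel fraction for a pose to be
#'   admissible.
#' @param pyramid optional smoothing pyramid from [patch_reg_pyramid()]
#'   (built on the fly when `NULL`); coarse search runs against blurred
#'   copies of the volume to widen the capture range.
#' @param profile `"fast"` or `"robust"` (see Details).
#' @param search_range capture range around the warm start (degrees / mm
#'   per parameter); a flat 2D patch admits spurious high-similarity
#'   matches on distant oblique planes, so the search is bounded.
#' @return A `pvr_registration` result; `converged = FALSE` with the warm
#'   start retained when the patch is degenerate.
#' @export
register_patch_to_volume <- function(patch, volume, stack, psf = NULL,
                                     sampling = c("linear", "psf"),
                                     profile = c("fast", "robust"),
                                     steps = c(1, 0.5, 0.25, 0.1),
                                     min_overlap = 0.5, pyramid = NULL,
                                     search_range = NULL,
                                     min_gain = 1e-3) {
  sampling <- match.arg(sampling)
  profile <- match.arg(profile)
  if (is.null(search_range))
    search_range <- if (profile == "robust") 9 else 3
  pix3 <- patch_pixel_matrix(patch)
  y <- patch$y
  if (!isTRUE(patch$registrable) || sd(y) == 0)
    return(registration_result(patch$transform, NA_real_, FALSE, 0L))
  centroid <- colMeans(voxel_to_world(stack, t(pix3)))
  tr0 <- rebase_center(patch$transform, centroid)
  par0 <- c(tr0$rotation, tr0$translation)
  make_f <- function(vol) {
    if (sampling == "psf")
      function(p) cc_patch_pose_psf(vol, stack, pix3, y, p, centroid, psf,
                                    min_overlap)
    else
      function(p) cc_patch_pose(vol, stack, pix3, y, p, centroid,
                                min_overlap)
  }
  f_fine <- make_f(volume)
  v0 <- f_fine(par0)
  if (!is.finite(v0))
    return(registration_result(patch$transform, NA_real_, FALSE, 0L))
  evals <- 0L
  lo <- par0 - search_range
  hi <- par0 + search_range
  par <- par0

  if (profile == "robust") {
    # minimized objective with a hard capture-range wall
    fmin <- function(p) {
      if (max(abs(p - par0)) > search_range) return(1)
      v <- f_fine(p)
      if (!is.finite(v)) 1 else -v
    }
    offs <- as.matrix(expand.grid(c(0, -3, 3, -6, 6), c(0, -3, 3, -6, 6)))
    best <- NULL
    for (s in seq_len(nrow(offs))) {
      s0 <- par0
      s0[1:2] <- s0[1:2] + offs[s, ]
      o <- stats::optim(s0, fmin, method = "Nelder-Mead",
                        control = list(maxit = 120, parscale = rep(2, 6)))
      evals <- evals + o$counts[1]
      if (is.null(best) || o$value < best$value) best <- o
    }
    o <- stats::optim(best$par, fmin, method = "Nelder-Mead",
                      control = list(maxit = 400, parscale = rep(1, 6),
                                     reltol = 1e-10))
    evals <- evals + o$counts[1]
    if (o$value > best$value) o <- best
    # re-inflate the simplex once: escapes shallow premature collapses
    o2 <- stats::optim(o$par, fmin, method = "Nelder-Mead",
                       control = list(maxit = 300, parscale = rep(0.5, 6),
                                      reltol = 1e-10))
    evals <- evals + o2$counts[1]
    if (o2$value < o$value) o <- o2
    par <- o$par
    res <- coord_descent_rigid(par, f_fine,
                               steps = c(1, 0.5, 0.25, 0.1, 0.05),
                               lower = lo, upper = hi)
    evals <- evals + res$evals
    if (sampling == "linear" && !is.null(psf)) {
      # final refinement under the full PSF forward model: acquired
      # pixels are thick-slice averages, and the interpolated objective
      # carries a small out-of-plane bias the simulated one does not
      fps <- function(q) cc_patch_pose_psf(volume, stack, pix3, y, q,
                                           centroid, psf, min_overlap)
      v0p <- fps(par0)
      resp <- coord_descent_rigid(res$par, fps,
                                  steps = c(0.4, 0.2, 0.1, 0.05),
                                  lower = lo, upper = hi)
      evals <- evals + resp$evals
      if (is.finite(resp$value) &&
          (!is.finite(v0p) || resp$value >= v0p)) {
        return(registration_result(
          rigid_transform(resp$par[1:3], resp$par[4:6], centroid),
          resp$value, TRUE, evals))
      }
    }
  } else {
    if (is.null(pyramid)) pyramid <- patch_reg_pyramid(volume)
    lvl_steps <- list(c(4, 2), c(2, 1))
    for (l in seq_along(pyramid)) {
      res <- coord_descent_rigid(par, make_f(pyramid[[l]]),
                                 steps = lvl_steps[[min(l, 2L)]],
                                 lower = lo, upper = hi)
      par <- res$par
      evals <- evals + res$evals
    }
    res <- coord_descent_rigid(par, f_fine, steps = steps,
                               lower = lo, upper = hi)
    evals <- evals + res$evals
  }
  # accept only a clear improvement over the warm start: against a still
  # blurry reconstruction, marginal CC gains at displaced poses are noise
  if (!is.finite(res$value) || res$value < v0 + min_gain)
    return(registration_result(rebase_center(patch$transform, centroid), v0,
                               TRUE, evals))
  registration_result(rigid_transform(res$par[1:3], res$par[4:6], centroid),
                      res$value, TRUE, evals)
}

#' Smoothing pyramid for patch registration
#'
#' Box-blurred copies of the reconstruction (strong then mild smoothing)
#' used for the coarse search levels of [register_patch_to_volume()].
#' Build once per outer iteration and share across patches.
#'
#' @param volume A [pvr_volume()].
#' @param levels number of blurred levels (>= 0).
#' @export
patch_reg_pyramid <- function(volume, levels = 2L) {
  if (levels < 1L) return(list())
  d <- vol_dim(volume)
  out <- list()
  radii <- c(2L, 1L)[seq_len(min(levels, 2L))]
  for (r in radii) {
    v <- volume
    v$voxels <- array(cpp_box_blur3(as.numeric(volume$voxels), d, r, 1L), d)
    out[[length(out) + 1L]] <- v
  }
  out
}
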