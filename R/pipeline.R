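#' Pipeline configuration
#'
#' Collects every tunable of the reconstruction loop with its default.
#' Defaults follow the standard whole-uterus settings: square patches of
#' 32 px with stride 16, superpixels of step 16 dilated by 60% of the
#' step, multi-scale factor 1.5 over 4 scales with 2 outer iterations per
#' scale (fixed-scale variants run 2 outer iterations), edge threshold
#' `delta = 150`, 7 SR inner iterations, and an isotropic 1.25 mm target
#' grid.
#'
#' @param variant `"svr"`, `"square"`, `"superpixel"`, or
#'   `"ms-superpixel"`.
#' @param patch_size square patch edge / superpixel step (pixels).
#' @param stride square-patch stride (pixels).
#' @param gamma superpixel dilation (percent of the step by default).
#' @param gamma_units `"percent"` or `"px"`.
#' @param compactness SLIC compactness (`NULL` = adaptive).
#' @param scale_factor,n_scales,iters_per_scale multi-scale schedule;
#'   fixed-scale variants use `n_scales = 1`.
#' @param target_spacing isotropic voxel size of the reconstruction (mm).
#' @param delta edge threshold of the regularizer (intensity units).
#' @param lambda0_factor multiplier of `delta^2` for the initial lambda.
#' @param sr_iters SR inner iterations per outer iteration.
#' @param sr_step0 initial SR step size for backtracking.
#' @param psf_epsilon Taylor truncation bound of the PSF.
#' @param psf_prune relative footprint pruning threshold used during
#'   reconstruction (0 disables).
#' @param reg_sampling `"linear"` or `"psf"` similarity sampling for
#'   patch registration.
#' @param reg_profile `"fast"` (warm-started coordinate descent) or
#'   `"robust"` (multi-start simplex; about tenfold cost).
#' @param reg_steps registration step schedule (deg / mm).
#' @param min_overlap minimum in-field fraction for a registration pose.
#' @param em_threshold patch exclusion threshold on `p_hat`.
#' @param mask optional [pvr_volume()] region mask (nonzero = inside).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return A list of class `pvr_config`.
#' @export
pvr_config <- function(variant = c("square", "svr", "superpixel",
                                   "ms-superpixel"),
                       patch_size = NULL, stride = NULL, gamma = 60,
                       gamma_units = "percent", compactness = NULL,
                       scale_factor = 1.5, n_scales = NULL,
                       iters_per_scale = 2, target_spacing = 1.25,
                       delta = 150, lambda0_factor = 0.8, sr_iters = 7L,
                       sr_step0 = 1, psf_epsilon = 1e-6, psf_prune = 0.01,
                       reg_sampling = "linear", reg_profile = "fast",
                       reg_steps = c(1, 0.5, 0.25, 0.1),
                       min_overlap = 0.5, em_threshold = 0.5, mask = NULL,
                       seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(patch_size))
    patch_size <- switch(variant, square = 32L, svr = NA_integer_,
                         superpixel = 16L, `ms-superpixel` = 16L)
  if (is.null(stride)) stride <- if (identical(variant, "square"))
    as.integer(patch_size / 2) else NA_integer_
  if (is.null(n_scales))
    n_scales <- if (variant == "ms-superpixel") 4L else 1L
  structure(list(variant = variant, patch_size = patch_size, stride = stride,
                 gamma = gamma, gamma_units = gamma_units,
                 compactness = compactness, scale_factor = scale_factor,
                 n_scales = n_scales, iters_per_scale = iters_per_scale,
                 target_spacing = target_spacing, delta = delta,
                 lambda0_factor = lambda0_factor, sr_iters = sr_iters,
                 sr_step0 = sr_step0, psf_epsilon = psf_epsilon,
                 psf_prune = psf_prune, reg_sampling = reg_sampling, reg_profile = reg_profile,
                 reg_steps = reg_steps, min_overlap = min_overlap,
                 em_threshold = em_threshold, mask = mask,
                 seed = as.integer(seed)),
            class = "pvr_config")
}

# reconstruction grid: isotropic target covering the template stack FOV
recon_grid <- function(template, spacing) {
  b <- world_bounds(template)
  nd <- pmax(2L, as.integer(floor((b$max - b$min) / spacing)) + 1L)
  pvr_volume(array(0, nd), spacing = rep(spacing, 3), origin = b$min)
}

# extract patches for every stack at one scale of a config
extract_all_patches <- function(stacks, config, a_scale, scale_index,
                                masks = NULL) {
  mode <- switch(config$variant, svr = "slice", square = "square",
                 superpixel = "superpixel", `ms-superpixel` = "superpixel")
  out <- list()
  for (s in seq_along(stacks)) {
    sp <- if (mode == "superpixel")
      superpixel_params(a = a_scale, compactness = config$compactness,
                        gamma = config$gamma,
                        gamma_units = config$gamma_units)
    else superpixel_params()
    out <- c(out, extract_stack_patches(
      stacks[[s]], s, mode = mode, a = a_scale,
      omega = if (mode == "square") min(config$stride, a_scale) else a_scale,
      sp_params = sp, scale_index = scale_index,
      mask = if (is.null(masks)) NULL else masks[[s]]))
  }
  out
}

#' Patch-count and pixel-overhead accounting
#'
#' Overhead relative to processing each acquired pixel once:
#' `overhead_pixel_percent = 100 * (sum of patch mask sizes - unique
#' covered pixels) / unique covered pixels`. An exact tiling
#' (`omega = a`, or undilated superpixels) has 0% overhead.
#'
#' @param patches list of `pvr_patch` (all stacks/scales, with
#'   multiplicity if scales repeat).
#' @param stacks the stacks the patches were extracted from.
#' @return A list with `n_patches`, `overhead_pixel_percent`,
#'   `total_pixels`, `unique_pixels`.
#' @export
count_overhead <- function(patches, stacks) {
  total <- sum(vapply(patches, function(p) nrow(p$pix), numeric(1)))
  keys <- unlist(lapply(patches, function(p) {
    d <- vol_dim(stacks[[p$stack_id]])
    (p$pix[, 1] + d[1] * (p$pix[, 2] + d[2] * as.numeric(p$slice_index))) +
      prod(d) * (p$stack_id - 1)
  }), use.names = FALSE)
  uniq <- length(unique(keys))
  list(n_patches = length(patches),
       overhead_pixel_percent = if (uniq > 0) 100 * (total - uniq) / uniq
       else 0,
       total_pixels = total, unique_pixels = uniq)
}

#' Full patch-to-volume reconstruction
#'
#' Runs the complete loop: template selection, global intensity matching,
#' 3D-3D stack initialization, then per scale (patch extraction,
#' patch-to-volume registration, EM outlier classification,
#' regularized super-resolution). The `"svr"` variant uses whole slices
#' as patches and reproduces classical slice-to-volume behaviour; the
#' pipeline is deterministic given its inputs and configuration.
#'
#' @param stacks list of [pvr_volume()] stacks (>= 1; >= 2 recommended).
#' @param config A [pvr_config()].
#' @param template_index optional user override of the template stack.
#' @param verbose print per-iteration progress.
#' @return A list of class `pvr_recon` with elements `volume`
#'   (reconstruction), `rigidity` (rigidity/uncertainty map), `manifest`
#'   (per-iteration log, per-patch table, overhead accounting, config),
#'   and `patches` (final-scale patches with final transforms).
#' @export
pvr_reconstruct <- function(stacks, config = pvr_config(),
                            template_index = NULL, verbose = FALSE) {
  if (length(stacks) == 0L) stop("no input stacks")
  if (length(stacks) == 1L)
    warning("single-stack reconstruction is poorly constrained")
  for (s in stacks)
    if (!inherits(s, "pvr_volume")) stop("stacks must be pvr_volume objects")

  ## initialization: template, intensity matching, 3D-3D alignment
  tmpl <- if (is.null(template_index)) select_template_stack(stacks)
          else as.integer(template_index)
  stacks <- match_intensities(stacks, tmpl)
  stack_tr <- vector("list", length(stacks))
  for (s in seq_along(stacks)) {
    stack_tr[[s]] <- if (s == tmpl) {
      d <- vol_dim(stacks[[s]])
      rigid_transform(center = as.numeric(voxel_to_world(stacks[[s]],
                                                         (d - 1) / 2)))
    } else {
      register_volume_3d(stacks[[s]], stacks[[tmpl]])$transform
    }
  }
  grid <- recon_grid(stacks[[tmpl]], config$target_spacing)
  in_plane <- stacks[[tmpl]]$spacing[1:2]
  psf <- psf_model(in_plane_fwhm = in_plane,
                   through_plane_fwhm = stacks[[tmpl]]$spacing[3],
                   epsilon = config$psf_epsilon)

  masks <- NULL
  if (!is.null(config$mask)) {
    masks <- lapply(stacks, function(s)
      resample(config$mask, s, NULL, "nearest")$voxels > 0)
  }

  ## multi-scale schedule
  sched <- if (config$variant == "ms-superpixel") {
    multiscale_schedule(config$patch_size, config$scale_factor,
                        config$n_scales, config$iters_per_scale)
  } else {
    data.frame(scale_index = 0L,
               a = if (config$variant == "svr") NA_integer_
                   else as.integer(config$patch_size),
               iterations = as.integer(config$iters_per_scale))
  }

  log_rows <- list()
  all_overhead <- list(n_patches = 0, total_pixels = 0)
  outer_k <- 0L
  em_st <- NULL
  state <- NULL
  patches <- NULL
  cache <- NULL
  yr <- range(unlist(lapply(stacks, function(s) range(s$voxels))))

  for (si in seq_len(nrow(sched))) {
    patches <- extract_all_patches(stacks, config, sched$a[si],
                                   sched$scale_index[si], masks)
    if (length(patches) == 0L) stop("no patches extracted (empty mask?)")
    # initialize patch transforms from the parent stack's transform,
    # re-centred on the patch centroid
    for (i in seq_along(patches)) {
      p <- patches[[i]]
      ctr <- colMeans(voxel_to_world(stacks[[p$stack_id]],
                                     cbind(p$pix, p$slice_index)))
      patches[[i]]$transform <- rebase_center(stack_tr[[p$stack_id]], ctr)
    }
    patches <- flag_low_variance(patches, stacks)

    if (is.null(state)) {
      cache <- sr_prepare(patches, stacks, grid, psf,
                          prune = config$psf_prune)
      vol0 <- sr_init(patches, cache, grid)
      state <- sr_state(vol0, attr(vol0, "confidence"),
                        lambda = lambda_schedule(config$delta, 0,
                                                 config$lambda0_factor),
                        delta = config$delta)
    }

    for (it in seq_len(sched$iterations[si])) {
      ## (1) register every patch against the frozen current volume
      n_reg <- 0L
      pyr <- patch_reg_pyramid(state$volume)
      for (i in seq_along(patches)) {
        p <- patches[[i]]
        if (!p$registrable) next
        res <- register_patch_to_volume(
          p, state$volume, stacks[[p$stack_id]], psf,
          sampling = config$reg_sampling, profile = config$reg_profile,
          steps = config$reg_steps, min_overlap = config$min_overlap,
          pyramid = pyr)
        if (res$converged) {
          patches[[i]]$transform <- res$transform
          n_reg <- n_reg + 1L
        }
      }
      ## (2) rebuild footprints, EM classification, SR descent
      cache <- sr_prepare(patches, stacks, grid, psf,
                          prune = config$psf_prune)
      x <- as.numeric(state$volume$voxels)
      em <- em_round(patches, cache, x, em_st,
                     threshold = config$em_threshold)
      patches <- em$patches
      em_st <- em$state
      state$lambda <- lambda_schedule(config$delta, outer_k,
                                      config$lambda0_factor)
      state <- sr_solve(state, patches, cache, n_iter = config$sr_iters,
                        step0 = config$sr_step0)
      outer_k <- outer_k + 1L

      oh <- count_overhead(patches, stacks)
      all_overhead$n_patches <- all_overhead$n_patches + oh$n_patches
      all_overhead$total_pixels <- all_overhead$total_pixels +
        oh$total_pixels
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        outer = outer_k, scale = sched$scale_index[si], a = sched$a[si],
        lambda = state$lambda,
        objective = utils::tail(attr(state, "trace"), 1),
        em_c = if (is.null(em_st)) NA_real_ else em_st$c,
        em_sigma2 = if (is.null(em_st)) NA_real_ else em_st$sigma2,
        n_patches = length(patches),
        n_registered = n_reg,
        n_excluded = sum(!vapply(patches, `[[`, logical(1), "included")))
      if (verbose)
        message(sprintf(
          "outer %d (scale %d): obj %.4g, c = %.3f, excluded %d/%d",
          outer_k, sched$scale_index[si],
          utils::tail(attr(state, "trace"), 1),
          if (is.null(em_st)) NA else em_st$c,
          sum(!vapply(patches, `[[`, logical(1), "included")),
          length(patches)))
    }
  }

  ## outputs: clamp to the observed input range, rigidity map, manifest
  out_vol <- state$volume
  out_vol$voxels <- pmin(pmax(out_vol$voxels, yr[1]), yr[2])
  rigidity <- build_rigidity_map(patches, cache, grid)
  patch_table <- do.call(rbind, lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    data.frame(id = i, stack = p$stack_id, slice = p$slice_index,
               scale = p$scale_index, n_pixels = nrow(p$pix),
               p_hat = p$p_hat, included = p$included,
               rot_x = p$transform$rotation[1],
               rot_y = p$transform$rotation[2],
               rot_z = p$transform$rotation[3],
               t_x = p$transform$translation[1],
               t_y = p$transform$translation[2],
               t_z = p$transform$translation[3])
  }))
  final_oh <- count_overhead(patches, stacks)
  manifest <- list(config = config, template_index = tmpl,
                   seed = config$seed,
                   log = do.call(rbind, log_rows), patch_table = patch_table,
                   n_patches_processed = all_overhead$n_patches,
                   pixels_processed = all_overhead$total_pixels,
                   final_overhead = final_oh,
                   stack_transforms = stack_tr)
  structure(list(volume = out_vol, rigidity = rigidity, manifest = manifest,
                 patches = patches, stacks = stacks, psf = psf, grid = grid),
            class = "pvr_recon")
}

#' @export
print.pvr_recon <- function(x, ...) {
  d <- vol_dim(x$volume)
  cat(sprintf("<pvr_recon> %s variant: %d x %d x %d @ %.3g mm\n",
              x$manifest$config$variant, d[1], d[2], d[3],
              x$volume$spacing[1]))
  cat(sprintf("  %d patches (%d excluded), %d outer iterations\n",
              nrow(x$manifest$patch_table),
              sum(!x$manifest$patch_table$included),
              nrow(x$manifest$log)))
  invisible(x)
}

#' Count processed patches for a variant without reconstructing
#'
#' Runs only the extraction stage of every outer iteration of the
#' variant's schedule and accumulates the processed-patch and
#' processed-pixel counts — the computational-overhead accounting used to
#' compare PVR variants.
#'
#' @param stacks list of [pvr_volume()] stacks.
#' @param config A [pvr_config()].
#' @param total_outer total outer iterations to account for; defaults to
#'   the variant's own schedule.
#' @return A list with `n_patches_processed`, `pixels_processed`,
#'   `overhead_pixel_percent` (per extraction), `n_patches_per_pass`.
#' @export
plan_patch_counts <- function(stacks, config, total_outer = NULL) {
  sched <- if (config$variant == "ms-superpixel") {
    multiscale_schedule(config$patch_size, config$scale_factor,
                        config$n_scales, config$iters_per_scale)
  } else {
    data.frame(scale_index = 0L,
               a = if (config$variant == "svr") NA_integer_
                   else as.integer(config$patch_size),
               iterations = as.integer(config$iters_per_scale))
  }
  # one entry per outer iteration, recycled/truncated to total_outer
  a_per_outer <- rep(sched$a, times = sched$iterations)
  sc_per_outer <- rep(sched$scale_index, times = sched$iterations)
  if (!is.null(total_outer)) {
    i <- (seq_len(total_outer) - 1L) %% length(a_per_outer) + 1L
    a_per_outer <- a_per_outer[i]
    sc_per_outer <- sc_per_outer[i]
  }
  n_proc <- 0; px_proc <- 0; per_pass <- integer(0); oh_last <- NULL
  seen <- list()
  for (o in seq_along(a_per_outer)) {
    key <- paste0(a_per_outer[o])
    if (is.null(seen[[key]])) {
      patches <- extract_all_patches(stacks, config, a_per_outer[o],
                                     sc_per_outer[o])
      seen[[key]] <- count_overhead(patches, stacks)
    }
    oh <- seen[[key]]
    oh_last <- oh
    per_pass <- c(per_pass, oh$n_patches)
    n_proc <- n_proc + oh$n_patches
    px_proc <- px_proc + oh$total_pixels
  }
  list(n_patches_processed = n_proc, pixels_processed = px_proc,
       overhead_pixel_percent = oh_last$overhead_pixel_percent,
       n_patches_per_pass = per_pass)
}
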