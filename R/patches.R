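#' Construct a patch
#'
#' A 2D pixel region within one acquired slice, carrying its current
#' rigid transform estimate, per-pixel inlier posteriors and patch
#' posterior. Used internally by the extraction functions and the
#' pipeline; exposed for testing and custom workflows.
#'
#' @param stack_id integer stack index.
#' @param slice_index 0-based slice index within the stack.
#' @param pix `n x 2` integer matrix of 0-based in-slice pixel coordinates.
#' @param intensities numeric vector of length `n`.
#' @param transform A [rigid_transform()] (current estimate).
#' @param scale_index which multi-scale pass created the patch.
#' @return An object of class `pvr_patch`.
#' @export
new_patch <- function(stack_id, slice_index, pix, intensities,
                      transform = rigid_transform(), scale_index = 0L) {
  pix <- matrix(as.integer(pix), ncol = 2)
  if (nrow(pix) == 0L) stop("patch mask must be non-empty")
  if (any(!is.finite(intensities))) stop("patch intensities must be finite")
  structure(list(stack_id = as.integer(stack_id),
                 slice_index = as.integer(slice_index),
                 pix = pix,
                 y = as.numeric(intensities),
                 transform = transform,
                 scale_index = as.integer(scale_index),
                 p = rep(1, nrow(pix)),
                 p_hat = 1,
                 included = TRUE,
                 registrable = TRUE),
            class = "pvr_patch")
}

#' Extract overlapping square patches from a slice
#'
#' Patches tile the slice on a stride-`omega` lattice starting at pixel
#' `(0, 0)`; boundary patches are cropped to the image. With
#' `omega < a` every interior pixel belongs to `ceiling(a/omega)^2`
#' patches; with `omega == a` the patches partition the slice.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param a patch edge length in pixels (>= 4).
#' @param omega stride in pixels, `1 <= omega <= a`.
#' @return A list of 2-column 0-based pixel-coordinate matrices, one per
#'   patch position (row-major over lattice positions).
#' @examples
#' masks <- extract_square_patches(matrix(0, 32, 32), a = 32, omega = 16)
#' length(masks)  # 4 lattice positions
#' @export
extract_square_patches <- function(slice, a, omega) {
  if (a < 4) stop("patch edge length a must be at least 4")
  if (omega < 1 || omega > a)
    stop("stride omega must satisfy 1 <= omega <= a (coverage gap otherwise)")
  nr <- nrow(slice); nc <- ncol(slice)
  starts_u <- seq.int(0L, max(0L, nr - 1L), by = as.integer(omega))
  starts_v <- seq.int(0L, max(0L, nc - 1L), by = as.integer(omega))
  out <- list()
  for (sv in starts_v)
    for (su in starts_u) {
      us <- su:min(su + a - 1L, nr - 1L)
      vs <- sv:min(sv + a - 1L, nc - 1L)
      out[[length(out) + 1L]] <-
        cbind(rep(us, times = length(vs)), rep(vs, each = length(us)))
    }
  out
}

#' Superpixel parameters
#'
#' @param a grid step / nominal superpixel size in pixels (>= 4).
#' @param compactness SLIC compactness `t`; `NULL` scales with the slice
#'   dynamic range at extraction time (`0.1 *` range), keeping the
#'   segmentation invariant to global affine intensity rescaling.
#' @param gamma dilation amount, in pixels or percent of `a` depending on
#'   `gamma_units`.
#' @param gamma_units `"percent"` (default, radius = `round(gamma/100 * a)`)
#'   or `"px"`.
#' @param iterations SLIC refinement iterations.
#' @return An object of class `pvr_sp_params`.
#' @export
superpixel_params <- function(a = 16, compactness = NULL, gamma = 60,
                              gamma_units = c("percent", "px"),
                              iterations = 10L) {
  gamma_units <- match.arg(gamma_units)
  if (a < 4) stop("superpixel step a must be at least 4")
  if (!is.null(compactness) && compactness <= 0)
    stop("compactness must be positive")
  if (gamma < 0) stop("gamma must be nonnegative")
  structure(list(a = a, compactness = compactness, gamma = gamma,
                 gamma_units = gamma_units, iterations = as.integer(iterations)),
            class = "pvr_sp_params")
}

gamma_pixels <- function(params) {
  if (params$gamma_units == "percent")
    as.integer(round(params$gamma / 100 * params$a))
  else as.integer(round(params$gamma))
}

#' SLIC superpixel segmentation of a slice
#'
#' Centroids are initialized on a regular grid of spacing `a` (one seed
#' per `a x a` cell) and refined by iterative assignment minimizing the
#' joint distance `D = sqrt(d_c^2 + (d_s/a)^2 t^2)` within a `2a x 2a`
#' search window, where `d_c` and `d_s` are the intensity and spatial
#' Euclidean distances and `t` the compactness. Orphaned connected
#' components are merged into the largest adjacent label so regions are
#' connected.
#'
#' @param slice 2D numeric matrix.
#' @param params A [superpixel_params()].
#' @return Integer matrix of 1-based labels forming a partition of the
#'   slice.
#' @export
extract_superpixels <- function(slice, params = superpixel_params()) {
  if (any(!is.finite(slice))) stop("slice intensities must be finite")
  if (nrow(slice) <= params$a || ncol(slice) <= params$a)
    stop("image must be larger than the superpixel step per axis")
  t <- params$compactness
  if (is.null(t)) {
    rg <- diff(range(slice))
    t <- if (rg > 0) 0.1 * rg else 1
  }
  cpp_slic(slice, params$a, t, params$iterations)
}

#' Dilate superpixel labels into overlapping patch masks
#'
#' Each label's mask is morphologically dilated by a flat square
#' structuring element of radius `gamma` pixels; `gamma = 0` returns the
#' partition unchanged.
#'
#' @param labels integer label matrix from [extract_superpixels()].
#' @param gamma dilation radius in pixels (>= 0).
#' @return A list of 2-column 0-based pixel-coordinate matrices, one per
#'   label.
#' @export
dilate_superpixels <- function(labels, gamma = 0) {
  if (gamma < 0) stop("gamma must be nonnegative")
  gamma <- as.integer(round(gamma))
  labs <- sort(unique(as.integer(labels)))
  out <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    mask <- labels == labs[i]
    if (gamma > 0) mask <- cpp_dilate_mask(mask, gamma)
    w <- which(mask, arr.ind = TRUE)
    out[[i]] <- cbind(as.integer(w[, 1] - 1L), as.integer(w[, 2] - 1L))
  }
  out
}

#' Multi-scale patch schedule
#'
#' Scale `i` uses patch size `a_i = round(a0 * factor^i)`; patch
#' extraction is re-invoked at every scale. `factor = 1` yields the
#' fixed-scale variant.
#'
#' @param a0 initial patch size in pixels (>= 4).
#' @param factor scale multiplier per scale (>= 1).
#' @param n_scales number of scales.
#' @param iterations_per_scale outer (registration + SR) iterations run at
#'   each scale.
#' @return A data.frame with columns `scale_index` (0-based), `a`, and
#'   `iterations`.
#' @examples
#' multiscale_schedule(16, 1.5, 4)  # a = 16, 24, 36, 54
#' @export
multiscale_schedule <- function(a0 = 16, factor = 1.5, n_scales = 4,
                                iterations_per_scale = 2) {
  if (a0 < 4) stop("a0 must be at least 4")
  if (factor < 1) stop("factor must be >= 1")
  i <- seq_len(n_scales) - 1
  data.frame(scale_index = i,
             a = as.integer(round(a0 * factor^i)),
             iterations = as.integer(iterations_per_scale))
}

# Build pvr_patch objects for every slice of a stack.
# mode "square": masks from extract_square_patches(a, omega);
# mode "superpixel": dilated SLIC labels; mode "slice": one whole-slice
# patch (the SVR limit). `mask` optionally restricts pixels (stack-grid
# logical array).
extract_stack_patches <- function(stack, stack_id, mode = "square",
                                  a = 32, omega = 16,
                                  sp_params = superpixel_params(),
                                  scale_index = 0L, mask = NULL) {
  d <- vol_dim(stack)
  patches <- list()
  for (k in seq_len(d[3])) {
    slice <- stack$voxels[, , k]
    masks <- switch(mode,
      slice = list(as.matrix(expand.grid(0:(d[1] - 1L), 0:(d[2] - 1L)))),
      square = extract_square_patches(slice, a, omega),
      superpixel = {
        if (sp_params$a >= min(d[1:2])) {
          # a superpixel step at or beyond the image size degenerates to
          # a single whole-slice segment
          list(as.matrix(expand.grid(0:(d[1] - 1L), 0:(d[2] - 1L))))
        } else {
          labs <- extract_superpixels(slice, sp_params)
          dilate_superpixels(labs, gamma_pixels(sp_params))
        }
      },
      stop("unknown patch mode"))
    for (m in masks) {
      if (!is.null(mask)) {
        keep <- mask[cbind(m[, 1] + 1L, m[, 2] + 1L, k)]
        m <- m[keep, , drop = FALSE]
        if (nrow(m) == 0L) next
      }
      y <- slice[cbind(m[, 1] + 1L, m[, 2] + 1L)]
      patches[[length(patches) + 1L]] <-
        new_patch(stack_id, k - 1L, m, y, scale_index = scale_index)
    }
  }
  patches
}

# Flag patches that carry too little information to be registered:
# near-zero intensity variance relative to the slice, or a mask dominated
# by background (air), whose pose is ambiguous. They keep their
# stack-level transform and still feed the SR data term.
flag_low_variance <- function(patches, stacks, rel_tol = 1e-6,
                              min_foreground = 0.3) {
  slice_var <- lapply(stacks, function(s)
    apply(s$voxels, 3, function(x) var(as.numeric(x))))
  fg_thr <- vapply(stacks, function(s)
    0.1 * quantile(as.numeric(s$voxels), 0.99, names = FALSE), numeric(1))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    sv <- slice_var[[p$stack_id]][p$slice_index + 1L]
    patches[[i]]$registrable <-
      is.finite(sv) && sv > 0 && var(p$y) > rel_tol * sv &&
      mean(p$y > fg_thr[p$stack_id]) >= min_foreground
  }
  patches
}
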