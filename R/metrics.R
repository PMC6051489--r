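#' Cross-correlation between two images
#'
#' Mean over pixels of the standardized intensity product
#' `(I - mu_I)(I~ - mu_I~) / (sigma_I sigma_I~)` (population standard
#' deviations), invariant under affine intensity rescaling of either
#' image.
#'
#' @param I,I_tilde numeric arrays of identical shape.
#' @return Value in `[-1, 1]`, or `NA` (with attribute `reason`) when
#'   either image has zero variance.
#' @export
cc_metric <- function(I, I_tilde) {
  a <- as.numeric(I); b <- as.numeric(I_tilde)
  if (length(a) != length(b)) stop("images must have the same shape")
  n <- length(a)
  va <- mean(a^2) - mean(a)^2
  vb <- mean(b^2) - mean(b)^2
  if (va <= 0 || vb <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero variance"
    return(out)
  }
  mean((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(I_max^2 / MSE)` in dB, with `I_max` the maximum intensity of
#' the reference image `I` (overridable via `i_max`). `MSE = 0` yields
#' `Inf`.
#'
#' @param I reference image.
#' @param I_tilde comparison image of the same shape.
#' @param i_max reference maximum (defaults to `max(I)`).
#' @export
psnr_metric <- function(I, I_tilde, i_max = NULL) {
  a <- as.numeric(I); b <- as.numeric(I_tilde)
  if (length(a) != length(b)) stop("images must have the same shape")
  if (is.null(i_max)) i_max <- max(a)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(i_max^2 / mse)
}

#' Structural similarity index with DSSIM heat map
#'
#' Local SSIM on sliding windows,
#' `SSIM = (2 mu_I mu_I~ + c1)(2 cov + c2) /
#' ((mu_I^2 + mu_I~^2 + c1)(var_I + var_I~ + c2))` with
#' `c1 = (k1 L)^2`, `c2 = (k2 L)^2` and `L` the dynamic range of `I`.
#' The mean SSIM averages the local map; the DSSIM map is
#' `(1 - SSIM_local) / 2`.
#'
#' @param I,I_tilde 2D numeric matrices of identical shape.
#' @param k1,k2 stabilization constants (defaults 0.01 and 0.03).
#' @param window window edge length in pixels (uniform window).
#' @param L dynamic range; defaults to `max(I) - min(I)`.
#' @return A list with `ssim` (mean), `dssim_map` (matrix in `[0, 1]`),
#'   `window`.
#' @export
ssim_metric <- function(I, I_tilde, k1 = 0.01, k2 = 0.03, window = 7L,
                        L = NULL) {
  if (!all(dim(I) == dim(I_tilde))) stop("images must have the same shape")
  if (window > min(dim(I))) stop("window larger than image")
  if (is.null(L)) L <- diff(range(I))
  if (L <= 0) L <- 1
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  mux <- cpp_box_mean(I, window)
  muy <- cpp_box_mean(I_tilde, window)
  sxx <- cpp_box_mean(I * I, window) - mux^2
  syy <- cpp_box_mean(I_tilde * I_tilde, window) - muy^2
  sxy <- cpp_box_mean(I * I_tilde, window) - mux * muy
  ssim_map <- ((2 * mux * muy + c1) * (2 * sxy + c2)) /
    ((mux^2 + muy^2 + c1) * (sxx + syy + c2))
  dssim <- (1 - ssim_map) / 2
  list(ssim = mean(ssim_map), dssim_map = dssim, window = window)
}

# mean 2D SSIM over the slices of a 3D array (pixel-count weighted; all
# slices share a shape so this is a plain mean), using the global dynamic
# range of the reference volume
ssim_volume <- function(I, I_tilde, window = 7L) {
  L <- diff(range(I))
  vals <- vapply(seq_len(dim(I)[3]), function(k)
    ssim_metric(I[, , k], I_tilde[, , k], window = window, L = L)$ssim,
    numeric(1))
  mean(vals)
}

#' Reference-based reconstruction metrics against a ground-truth volume
#'
#' Resamples the ground truth onto the reconstruction grid and computes
#' CC and PSNR over the full grid plus mean slice-wise SSIM. This is the
#' evaluation path for synthetic experiments where the motion-free
#' phantom is available.
#'
#' @param recon Reconstructed [pvr_volume()].
#' @param truth Ground-truth [pvr_volume()].
#' @param window SSIM window.
#' @return A list with `psnr`, `ssim`, `cc`, and `n_pixels`.
#' @export
reference_metrics <- function(recon, truth, window = 7L) {
  tr <- resample(truth, recon, NULL, "linear")
  infield <- attr(tr, "infield")
  a <- tr$voxels
  b <- recon$voxels
  keep <- which(infield)
  list(psnr = psnr_metric(a[keep], b[keep], i_max = max(a[keep])),
       ssim = ssim_volume(a, b, window = window),
       cc = cc_metric(a[keep], b[keep]),
       n_pixels = length(keep))
}

#' Reference-free evaluation against the acquired slices
#'
#' Treats the acquired in-plane slices as gold standard: for every slice,
#' the corresponding image is simulated from the reconstruction through
#' the PSF and the final patch transforms (overlapping simulated patches
#' are averaged), and CC / PSNR / SSIM are computed between acquired and
#' simulated pixels. Slice metrics are pixel-count weighted into a volume
#' report; out-of-field pixels are excluded.
#'
#' @param stacks list of acquired [pvr_volume()] stacks (intensity-matched
#'   versions used for reconstruction).
#' @param recon Reconstructed [pvr_volume()].
#' @param patches final-scale patches with their final transforms (e.g.
#'   from [pvr_reconstruct()]).
#' @param psf A [psf_model()].
#' @param window SSIM window.
#' @return A list with volume-level `psnr`, `ssim`, `cc`, `n_pixels`, and
#'   a per-slice data.frame `slices`.
#' @export
evaluate_reconstruction <- function(stacks, recon, patches, psf,
                                    window = 7L) {
  cache <- sr_prepare(patches, stacks, recon, psf)
  x <- as.numeric(recon$voxels)
  sims <- simulate_all(x, patches, cache)
  # composite simulated slices: average overlapping patch simulations
  acc <- lapply(stacks, function(s) array(0, vol_dim(s)))
  cnt <- lapply(stacks, function(s) array(0, vol_dim(s)))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    cov <- cache[[i]]$covered
    if (!any(cov)) next
    ind <- cbind(p$pix[cov, 1] + 1L, p$pix[cov, 2] + 1L,
                 p$slice_index + 1L)
    acc[[p$stack_id]][ind] <- acc[[p$stack_id]][ind] + sims[[i]][cov]
    cnt[[p$stack_id]][ind] <- cnt[[p$stack_id]][ind] + 1
  }
  rows <- list()
  for (s in seq_along(stacks)) {
    d <- vol_dim(stacks[[s]])
    for (k in seq_len(d[3])) {
      n_eval <- sum(cnt[[s]][, , k] > 0)
      if (n_eval == 0) next
      simsl <- acc[[s]][, , k]
      csl <- cnt[[s]][, , k]
      simsl[csl > 0] <- simsl[csl > 0] / csl[csl > 0]
      obs <- stacks[[s]]$voxels[, , k]
      sel <- csl > 0
      ccv <- cc_metric(obs[sel], simsl[sel])
      psnr <- psnr_metric(obs[sel], simsl[sel], i_max = max(obs))
      # SSIM needs the full 2D lattice; fill unevaluated pixels with the
      # observation so they contribute zero dissimilarity
      simfull <- simsl
      simfull[!sel] <- obs[!sel]
      ss <- ssim_metric(obs, simfull, window = window)$ssim
      rows[[length(rows) + 1L]] <-
        data.frame(stack = s, slice = k - 1L, cc = as.numeric(ccv),
                   psnr = psnr, ssim = ss, n_pixels = n_eval)
    }
  }
  if (length(rows) == 0L) stop("no evaluable slices (missing transforms?)")
  df <- do.call(rbind, rows)
  wts <- df$n_pixels / sum(df$n_pixels)
  finite_wmean <- function(v) {
    ok <- !is.na(v)   # +Inf (perfect PSNR) propagates; NA (undefined) drops
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * wts[ok]) / sum(wts[ok])
  }
  list(psnr = finite_wmean(df$psnr), ssim = finite_wmean(df$ssim),
       cc = finite_wmean(df$cc), n_pixels = sum(df$n_pixels), slices = df)
}
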