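#' Separable point-spread-function model
#'
#' The forward model blurring a high-resolution voxel into an acquired
#' pixel: in-plane, a truncated-Taylor sinc whose first zero falls at the
#' in-plane voxel size, windowed by a Gaussian (window FWHM = twice the
#' in-plane size) so that far side lobes vanish; through-plane, a Gaussian
#' slice profile with FWHM equal to the slice thickness. Negative sinc
#' lobes are clipped to zero so discretized footprints form convex
#' combinations. The number of retained Taylor terms is chosen so that the
#' Lagrange remainder bound stays below `epsilon` everywhere on the
#' support (the alternating-series remainder is bounded by the first
#' omitted term).
#'
#' @param in_plane_fwhm length-2 (or scalar) in-plane FWHM in mm,
#'   typically the in-plane voxel spacing.
#' @param through_plane_fwhm slice thickness in mm.
#' @param epsilon relative truncation error bound for the Taylor sinc.
#' @param support_radius mm cutoff beyond which the weight is exactly 0;
#'   default twice the largest voxel extent.
#' @param taylor_terms optional override for the number of retained terms.
#' @return An object of class `pvr_psf`.
#' @examples
#' psf <- psf_model(c(1.25, 1.25), 2.5)
#' psf_weight(c(0, 0, 0), psf)
#' @export
psf_model <- function(in_plane_fwhm = c(1.25, 1.25), through_plane_fwhm = 2.5,
                      epsilon = 1e-6, support_radius = NULL,
                      taylor_terms = NULL) {
  if (length(in_plane_fwhm) == 1L) in_plane_fwhm <- rep(in_plane_fwhm, 2)
  stopifnot(length(in_plane_fwhm) == 2, all(in_plane_fwhm > 0),
            through_plane_fwhm > 0)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("epsilon must be a positive number")
  if (is.null(support_radius))
    support_radius <- 2 * max(in_plane_fwhm, through_plane_fwhm)
  stopifnot(support_radius > 0)
  if (is.null(taylor_terms))
    taylor_terms <- taylor_terms_for(epsilon,
                                     pi * support_radius / min(in_plane_fwhm))
  structure(list(in_plane_fwhm = as.numeric(in_plane_fwhm),
                 through_plane_fwhm = as.numeric(through_plane_fwhm),
                 epsilon = epsilon,
                 support_radius = support_radius,
                 taylor_terms = as.integer(taylor_terms)),
            class = "pvr_psf")
}

#' @export
print.pvr_psf <- function(x, ...) {
  cat(sprintf(paste0("<pvr_psf> in-plane FWHM (%s) mm, through-plane %.3g mm,",
                     " support %.3g mm, %d Taylor terms (eps = %.1g)\n"),
              paste(signif(x$in_plane_fwhm, 4), collapse = ", "),
              x$through_plane_fwhm, x$support_radius, x$taylor_terms,
              x$epsilon))
  invisible(x)
}

# Smallest term count whose first omitted Taylor term of sinc stays
# below eps for |x| <= xmax.
taylor_terms_for <- function(eps, xmax) {
  n <- 2L
  repeat {
    # first omitted term: xmax^(2n) / (2n+1)!
    lt <- 2 * n * log(xmax) - lgamma(2 * n + 2)
    if (lt <= log(eps) || n > 200L) return(n)
    n <- n + 1L
  }
}

#' Truncated Taylor series of sinc(x) = sin(x)/x
#'
#' `1 - x^2/3! + x^4/5! - x^6/7! + ...`, truncated after `nterms` retained
#' terms (the leading 1 counts as the first).
#'
#' @param x numeric vector.
#' @param nterms number of retained terms.
#' @export
taylor_sinc <- function(x, nterms = 8L) {
  cpp_taylor_sinc(as.numeric(x), as.integer(nterms))
}

#' Evaluate the PSF weight at a slice-frame offset
#'
#' @param offset length-3 (mm) or `n x 3` matrix of offsets in slice
#'   coordinates: two in-plane components then the through-plane one.
#' @param model A [psf_model()].
#' @return Nonnegative weight(s); zero beyond the support radius.
#' @export
psf_weight <- function(offset, model) {
  o <- if (is.matrix(offset)) offset else matrix(offset, ncol = 3)
  f <- model$in_plane_fwhm
  u1 <- abs(o[, 1]) / f[1]
  u2 <- abs(o[, 2]) / f[2]
  s1 <- pmax(cpp_taylor_sinc(pi * u1, model$taylor_terms), 0)
  s2 <- pmax(cpp_taylor_sinc(pi * u2, model$taylor_terms), 0)
  # clip whole negative lobes (odd intervals of u), matching the
  # footprint discretization
  s1[(floor(u1) %% 2) == 1] <- 0
  s2[(floor(u2) %% 2) == 1] <- 0
  ln2x4 <- 4 * log(2)
  g <- exp(-(ln2x4 * o[, 1]^2 / (2 * f[1])^2 +
             ln2x4 * o[, 2]^2 / (2 * f[2])^2 +
             ln2x4 * o[, 3]^2 / model$through_plane_fwhm^2))
  w <- s1 * s2 * g
  w[rowSums(o^2) > model$support_radius^2] <- 0
  if (is.matrix(offset)) w else as.numeric(w)
}

# Discretized PSF footprint (CSR) of patch pixels over an HR grid.
# pixel_world: n x 3 world positions (reconstruction frame);
# axes: 3 x 3 slice-frame axes as unit columns in the reconstruction frame.
psf_footprint <- function(pixel_world, axes, grid, model, prune = 0) {
  cpp_footprint(t(pixel_world), axes, grid$origin, grid$spacing,
                grid$direction, vol_dim(grid),
                model$in_plane_fwhm[1], model$in_plane_fwhm[2],
                model$through_plane_fwhm, model$support_radius,
                model$taylor_terms, prune)
}
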