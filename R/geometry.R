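#' Image volume with physical geometry
#'
#' A 3D scalar grid together with its physical-space mapping. World
#' coordinates follow the voxel-centre convention:
#' `world = origin + direction %*% (spacing * index)` with 0-based indices,
#' so voxel `(0,0,0)` sits exactly at `origin`.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing length-3 positive numeric, mm per axis.
#' @param origin length-3 numeric, world position (mm) of the centre of
#'   voxel `(0,0,0)`.
#' @param direction 3x3 orthonormal matrix of axis directions.
#' @return An object of class `pvr_volume`.
#' @examples
#' vol <- pvr_volume(array(0, c(8, 8, 4)), spacing = c(1.25, 1.25, 2.5))
#' voxel_to_world(vol, c(0, 0, 0))
#' @export
pvr_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-9)
    stop("direction must be a 3x3 orthonormal matrix")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "pvr_volume")
}

#' @export
print.pvr_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<pvr_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

vol_dim <- function(volume) dim(volume$voxels)

#' Voxel-to-world mapping (4x4 homogeneous matrix)
#'
#' @param volume A [pvr_volume()].
#' @return 4x4 matrix mapping homogeneous 0-based voxel indices to mm.
#' @export
voxel_to_world_matrix <- function(volume) {
  m <- diag(4)
  m[1:3, 1:3] <- volume$direction %*% diag(volume$spacing)
  m[1:3, 4] <- volume$origin
  m
}

#' Map voxel indices to world coordinates
#'
#' @param volume A [pvr_volume()].
#' @param index numeric vector of length 3 or an `n x 3` matrix of 0-based
#'   (possibly fractional) voxel indices.
#' @return World coordinates (mm), same shape as `index`.
#' @export
voxel_to_world <- function(volume, index) {
  idx <- if (is.matrix(index)) t(index) else matrix(index, nrow = 3)
  w <- volume$direction %*% (volume$spacing * idx) + volume$origin
  if (is.matrix(index)) t(w) else as.numeric(w)
}

#' Map world coordinates to continuous voxel indices
#'
#' Exact inverse of [voxel_to_world()]; indices outside the grid are
#' returned unclamped.
#'
#' @inheritParams voxel_to_world
#' @param point numeric vector of length 3 or an `n x 3` matrix of world
#'   coordinates in mm.
#' @export
world_to_voxel <- function(volume, point) {
  p <- if (is.matrix(point)) t(point) else matrix(point, nrow = 3)
  v <- (t(volume$direction) %*% (p - volume$origin)) / volume$spacing
  if (is.matrix(point)) t(v) else as.numeric(v)
}

world_bounds <- function(volume) {
  d <- vol_dim(volume) - 1L
  corners <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  w <- voxel_to_world(volume, corners)
  list(min = apply(w, 2, min), max = apply(w, 2, max))
}

## ---- rigid / affine transforms ------------------------------------------

euler_to_rotation <- function(deg) {
  r <- deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cc <- cos(r[3]); sc <- sin(r[3])
  # R = Rz(c) %*% Ry(b) %*% Rx(a)
  matrix(c(cb * cc, cb * sc, -sb,
           cc * sa * sb - ca * sc, ca * cc + sa * sb * sc, cb * sa,
           sc * sa + ca * cc * sb, ca * sb * sc - cc * sa, ca * cb),
         nrow = 3)
}

rotation_to_euler <- function(R) {
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  b <- asin(sb)
  if (abs(abs(sb) - 1) < 1e-12) {
    # gimbal lock: fold the z rotation into x
    a <- atan2(-R[1, 2], R[2, 2])
    c <- 0
  } else {
    a <- atan2(R[3, 2], R[3, 3])
    c <- atan2(R[2, 1], R[1, 1])
  }
  c(a, b, c) * 180 / pi
}

#' Rigid 3D transform (Euler angles + translation about a centre)
#'
#' Maps a world point `x` to `R (x - center) + center + translation`,
#' where `R = Rz Ry Rx` from the Euler angles in degrees.
#'
#' @param rotation length-3 numeric, Euler angles in degrees (x, y, z).
#' @param translation length-3 numeric, mm.
#' @param center length-3 numeric, rotation centre in mm.
#' @return An object of class `pvr_rigid`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3)
  if (any(!is.finite(c(rotation, translation, center))))
    stop("rigid transform parameters must be finite")
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "pvr_rigid")
}

#' @export
print.pvr_rigid <- function(x, ...) {
  cat(sprintf("<pvr_rigid> rot (%s) deg, trans (%s) mm, centre (%s) mm\n",
              paste(signif(x$rotation, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

#' Affine 3D transform (homogeneous 4x4 matrix in mm space)
#'
#' @param matrix 4x4 numeric matrix with last row `(0, 0, 0, 1)`.
#' @return An object of class `pvr_affine`.
#' @export
affine_transform <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4)) ||
      max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("affine matrix must be 4x4 with last row (0,0,0,1)")
  if (!is.finite(rcond(matrix[1:3, 1:3])) || rcond(matrix[1:3, 1:3]) < 1e-12)
    stop("affine matrix is singular")
  structure(list(matrix = matrix), class = "pvr_affine")
}

#' Convert a transform to its 4x4 homogeneous matrix
#' @param transform A `pvr_rigid` or `pvr_affine`.
#' @export
as_affine_matrix <- function(transform) {
  if (inherits(transform, "pvr_affine")) return(transform$matrix)
  if (!inherits(transform, "pvr_rigid")) stop("not a transform")
  R <- euler_to_rotation(transform$rotation)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- transform$center + transform$translation -
    R %*% transform$center
  m
}

#' Apply a transform to world points
#' @param transform A `pvr_rigid` or `pvr_affine`.
#' @param points length-3 vector or `n x 3` matrix of mm coordinates.
#' @export
apply_transform <- function(transform, points) {
  m <- as_affine_matrix(transform)
  p <- if (is.matrix(points)) t(points) else matrix(points, nrow = 3)
  out <- m[1:3, 1:3] %*% p + m[1:3, 4]
  if (is.matrix(points)) t(out) else as.numeric(out)
}

#' Invert a transform
#' @param transform A `pvr_rigid` or `pvr_affine`.
#' @return A transform of the same class.
#' @export
invert_transform <- function(transform) {
  if (inherits(transform, "pvr_affine"))
    return(affine_transform(solve(transform$matrix)))
  R <- euler_to_rotation(transform$rotation)
  rigid_transform(rotation = rotation_to_euler(t(R)),
                  translation = as.numeric(-t(R) %*% transform$translation),
                  center = transform$center)
}

#' Compose two transforms (`first` applied first, then `second`)
#' @param second,first Transforms (`pvr_rigid` or `pvr_affine`).
#' @param center Rotation centre of the returned rigid transform when both
#'   inputs are rigid; defaults to the centre of `first`.
#' @export
compose_transforms <- function(second, first, center = NULL) {
  m <- as_affine_matrix(second) %*% as_affine_matrix(first)
  if (inherits(second, "pvr_rigid") && inherits(first, "pvr_rigid")) {
    if (is.null(center)) center <- first$center
    rigid_from_matrix(m, center)
  } else {
    affine_transform(m)
  }
}

# Express a rigid-motion 4x4 matrix as Euler + translation about `center`.
rigid_from_matrix <- function(m, center = c(0, 0, 0)) {
  R <- m[1:3, 1:3]
  rigid_transform(rotation = rotation_to_euler(R),
                  translation = as.numeric(m[1:3, 4] - center + R %*% center),
                  center = center)
}

# Re-express the same mapping about a new rotation centre.
rebase_center <- function(transform, center) {
  rigid_from_matrix(as_affine_matrix(transform), center)
}

## ---- resampling ----------------------------------------------------------

#' Resample a volume onto a target grid
#'
#' Values are pulled from `volume` at back-transformed target locations:
#' `transform` maps source world coordinates to target world coordinates,
#' so the source is sampled at `transform^-1(target_point)`.
#'
#' @param volume Source [pvr_volume()].
#' @param target A [pvr_volume()] providing the output geometry (its voxel
#'   values are ignored).
#' @param transform Optional `pvr_rigid`/`pvr_affine` (identity if `NULL`).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param background Value assigned to out-of-field voxels.
#' @return A [pvr_volume()] with the target geometry; attribute `infield`
#'   holds a logical array flagging voxels that mapped inside the source.
#' @export
resample <- function(volume, target, transform = NULL,
                     interpolation = c("linear", "nearest"),
                     background = 0) {
  interpolation <- match.arg(interpolation)
  m_t2w <- voxel_to_world_matrix(target)
  m_w2s <- solve(voxel_to_world_matrix(volume))
  tm <- if (is.null(transform)) diag(4) else solve(as_affine_matrix(transform))
  A <- (m_w2s %*% tm %*% m_t2w)[1:3, , drop = FALSE]
  td <- vol_dim(target)
  res <- cpp_resample(as.numeric(volume$voxels), vol_dim(volume), A,
                      as.integer(td), if (interpolation == "nearest") 0L else 1L,
                      background)
  out <- pvr_volume(array(res$values, td), target$spacing, target$origin,
                    target$direction)
  attr(out, "infield") <- array(res$infield, td)
  out
}

## ---- NIfTI and transform I/O --------------------------------------------

#' Read a NIfTI file as a `pvr_volume`
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  sp <- sqrt(colSums(m[1:3, 1:3]^2))
  dirm <- sweep(m[1:3, 1:3], 2, sp, "/")
  pvr_volume(a, spacing = sp, origin = m[1:3, 4], direction = dirm)
}

#' Write a `pvr_volume` to a NIfTI file
#' @param volume A [pvr_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  m <- diag(4)
  m[1:3, 1:3] <- volume$direction %*% diag(volume$spacing)
  m[1:3, 4] <- volume$origin
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a transform as plain text
#'
#' Rigid transforms are stored as 6 parameters (degrees, mm) plus centre;
#' affine transforms as a row-major 4x4 matrix.
#' @param transform A `pvr_rigid` or `pvr_affine`.
#' @param path Output file.
#' @export
write_transform <- function(transform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(transform, "pvr_rigid")) {
    writeLines(c("# pvr rigid transform",
                 "# rotation_deg_xyz translation_mm_xyz center_mm_xyz",
                 paste(format(c(transform$rotation, transform$translation,
                                transform$center), digits = 17),
                       collapse = " ")), con)
  } else {
    writeLines(c("# pvr affine transform (row-major 4x4, mm)",
                 apply(as_affine_matrix(transform), 1, function(r)
                   paste(format(r, digits = 17), collapse = " "))), con)
  }
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path Path to the text file.
#' @export
read_transform <- function(path) {
  ln <- readLines(path)
  head <- ln[1]
  vals <- ln[!startsWith(ln, "#")]
  if (grepl("rigid", head)) {
    x <- as.numeric(strsplit(trimws(vals[1]), "\\s+")[[1]])
    rigid_transform(x[1:3], x[4:6], x[7:9])
  } else {
    m <- do.call(rbind, lapply(vals, function(v)
      as.numeric(strsplit(trimws(v), "\\s+")[[1]])))
    affine_transform(m)
  }
}
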