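#' Volume grid: shape plus voxel-to-MNI affine
#'
#' A `volume_grid` ties a 3D voxel lattice to MNI millimetre space through a
#' 4x4 affine. All coordinate handling in the package goes through this affine;
#' nothing assumes a particular template resolution. Voxel indices are 0-based
#' everywhere a user sees them (matching NIfTI convention); internal linear
#' indices into flattened arrays are 1-based R indices.
#'
#' @param shape integer vector of 3 positive voxel counts.
#' @param affine 4x4 numeric matrix mapping homogeneous 0-based voxel indices
#'   to MNI mm. Must be invertible.
#' @return An object of class `volume_grid` with elements `shape`, `affine`
#'   and derived `voxel_size` (mm per axis).
#' @examples
#' g <- volume_grid(c(20, 24, 20), mni_affine(3, c(-30, -36, -30)))
#' voxel_to_mni(c(0, 0, 0), g)
#' @export
volume_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps * 100) {
    stop("affine matrix is singular", call. = FALSE)
  }
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) stop("voxel size must be positive", call. = FALSE)
  structure(
    list(shape = shape, affine = affine, voxel_size = voxel_size),
    class = "volume_grid"
  )
}

#' Diagonal MNI-style affine
#'
#' Convenience constructor for an axis-aligned affine with isotropic (or
#' per-axis) voxel size and a given mm coordinate for voxel (0, 0, 0).
#'
#' @param voxel_size mm per axis; scalar or length-3.
#' @param origin_mm MNI mm coordinate of voxel (0, 0, 0).
#' @return 4x4 numeric matrix.
#' @export
mni_affine <- function(voxel_size = 3, origin_mm = c(-90, -126, -72)) {
  vs <- rep_len(voxel_size, 3)
  aff <- diag(c(vs, 1))
  aff[1:3, 4] <- origin_mm
  aff
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Convert an MNI coordinate to the nearest voxel index
#'
#' @param coord MNI (x, y, z) in mm.
#' @param grid a [volume_grid()].
#' @return Integer 0-based voxel index triple. Errors (naming the coordinate)
#'   if the coordinate maps outside the grid.
#' @seealso [voxel_to_mni()]
#' @export
mni_to_voxel <- function(coord, grid) {
  stopifnot(inherits(grid, "volume_grid"), length(coord) == 3)
  v <- solve(grid$affine, c(as.numeric(coord), 1))[1:3]
  if (any(v < -0.5 | v > grid$shape - 0.5)) {
    stop(sprintf("MNI coordinate (%s) maps outside the grid",
                 paste(coord, collapse = ", ")), call. = FALSE)
  }
  as.integer(round(v))
}

#' Convert a 0-based voxel index to its MNI mm centre
#'
#' @param idx 0-based voxel index triple.
#' @inheritParams mni_to_voxel
#' @return Numeric (x, y, z) mm.
#' @export
voxel_to_mni <- function(idx, grid) {
  stopifnot(inherits(grid, "volume_grid"), length(idx) == 3)
  as.numeric(grid$affine %*% c(as.numeric(idx), 1))[1:3]
}

# mm centres of every voxel, as an (n_voxels x 3) matrix in R array order
# (first axis fastest). Row i corresponds to linear index i of a flattened
# array with dim = grid$shape.
grid_voxel_mm <- function(grid) {
  idx <- as.matrix(expand.grid(
    i = 0:(grid$shape[1] - 1),
    j = 0:(grid$shape[2] - 1),
    k = 0:(grid$shape[3] - 1)
  ))
  mm <- cbind(idx, 1) %*% t(grid$affine)
  mm[, 1:3, drop = FALSE]
}

# linear (1-based) index from a 0-based voxel triple
voxel_linear_index <- function(idx, grid) {
  1L + idx[1] + grid$shape[1] * (idx[2] + grid$shape[2] * idx[3])
}

# 0-based voxel triples from linear (1-based) indices; returns n x 3 matrix
linear_to_voxel <- function(lin, grid) {
  z <- (lin - 1L) %/% (grid$shape[1] * grid$shape[2])
  r <- (lin - 1L) %% (grid$shape[1] * grid$shape[2])
  y <- r %/% grid$shape[1]
  x <- r %% grid$shape[1]
  cbind(i = x, j = y, k = z)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Binary brain mask on a grid
#'
#' @param grid a [volume_grid()].
#' @param voxels logical array with dim equal to `grid$shape`, or a logical
#'   vector of length `prod(grid$shape)`.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "volume_grid"))
  voxels <- as.logical(voxels)
  stopifnot(length(voxels) == n_voxels(grid))
  voxels[is.na(voxels)] <- FALSE
  dim(voxels) <- grid$shape
  structure(list(grid = grid, voxels = voxels), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> ", sum(x$voxels), " / ", n_voxels(x$grid),
      " voxels set\n", sep = "")
  invisible(x)
}

mask_indices <- function(mask) which(as.vector(mask$voxels))

#' Read / write masks and 4D series as NIfTI-1
#'
#' Thin wrappers around RNifti keeping grid/affine bookkeeping consistent with
#' the rest of the package.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_mask()` a [brain_mask()]; `read_bold()` a [bold_series()].
#' @name nifti_io
NULL

# pixdim must carry the voxel size or RNifti rescales the stored xform
nifti_with_affine <- function(arr, grid, tr = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- grid$voxel_size
  if (!is.null(tr)) pd <- c(pd, tr)
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 4L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 4L))
  img
}

grid_from_nifti <- function(img) {
  d <- dim(img)
  xf <- RNifti::xform(img)
  attributes(xf) <- list(dim = c(4L, 4L))
  volume_grid(d[1:3], xf)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  g <- grid_from_nifti(img)
  brain_mask(g, as.vector(img) > 0)
}

#' @rdname nifti_io
#' @param mask a [brain_mask()].
#' @export
write_mask <- function(mask, path) {
  arr <- array(as.integer(mask$voxels), dim = mask$grid$shape)
  img <- nifti_with_affine(arr, mask$grid)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split a mask at the midsagittal plane
#'
#' Voxels are assigned by the sign of their MNI x coordinate (through the
#' affine, not the index). Voxels exactly on the midline (x == 0 mm) belong to
#' neither hemisphere and are dropped from both outputs, so the split never
#' double-counts. An empty hemisphere is allowed and reported with a warning.
#'
#' @param mask a non-empty [brain_mask()].
#' @return Named list with `left` and `right` [brain_mask()] objects.
#' @export
split_hemispheres <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!any(mask$voxels)) stop("mask is empty", call. = FALSE)
  x_mm <- grid_voxel_mm(mask$grid)[, 1]
  v <- as.vector(mask$voxels)
  left <- brain_mask(mask$grid, v & x_mm < 0)
  right <- brain_mask(mask$grid, v & x_mm > 0)
  if (!any(left$voxels)) warning("left hemisphere mask is empty")
  if (!any(right$voxels)) warning("right hemisphere mask is empty")
  list(left = left, right = right)
}
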