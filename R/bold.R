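#' BOLD time series on a volume grid
#'
#' The 4D data are stored internally as a volumes x voxels matrix (voxels in
#' R array order over the grid) together with the grid, repetition time,
#' per-volume censor flags (`TRUE` = retained) and an ordered record of the
#' preprocessing steps applied. Censoring is a mask, not a deletion: censored
#' volumes keep their slot so motion traces stay index-aligned, and every
#' correlation downstream excludes them.
#'
#' @param data numeric matrix (n_volumes x n_voxels) or 4D array (x, y, z, t).
#' @param grid a [volume_grid()].
#' @param tr repetition time in seconds, > 0.
#' @param censor logical per-volume retention flags; defaults to all retained.
#' @param steps character vector of applied preprocessing step labels.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, grid, tr, censor = NULL, steps = character()) {
  stopifnot(inherits(grid, "volume_grid"), tr > 0)
  if (length(dim(data)) == 4) {
    stopifnot(all(dim(data)[1:3] == grid$shape))
    nt <- dim(data)[4]
    data <- t(matrix(data, nrow = prod(grid$shape), ncol = nt))
  }
  data <- as.matrix(data)
  stopifnot(ncol(data) == n_voxels(grid))
  if (is.null(censor)) censor <- rep(TRUE, nrow(data))
  stopifnot(length(censor) == nrow(data))
  structure(
    list(data = data, grid = grid, tr = as.numeric(tr),
         censor = as.logical(censor), steps = as.character(steps)),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  cat("<bold_series> ", nrow(x$data), " volumes x ", ncol(x$data),
      " voxels, TR ", x$tr, " s, ", sum(!x$censor), " censored",
      if (length(x$steps)) paste0("\n  steps: ", paste(x$steps, collapse = " -> ")),
      "\n", sep = "")
  invisible(x)
}

n_volumes <- function(series) nrow(series$data)

record_step <- function(series, label) {
  if (!length(series$steps) || utils::tail(series$steps, 1) != label) {
    series$steps <- c(series$steps, label)
  }
  series
}

#' @rdname nifti_io
#' @param tr repetition time (seconds); taken from the NIfTI header pixdim[4]
#'   when not supplied.
#' @export
read_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  stopifnot(length(dim(img)) == 4)
  g <- grid_from_nifti(img)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  bold_series(array(as.numeric(img), dim = dim(img)), g, tr = tr)
}

#' @rdname nifti_io
#' @param series a [bold_series()].
#' @export
write_bold <- function(series, path) {
  arr <- array(t(series$data), dim = c(series$grid$shape, n_volumes(series)))
  img <- nifti_with_affine(arr, series$grid, tr = series$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write 6-parameter motion traces
#'
#' Motion traces are TSV files with six columns in SPM order: three
#' translations (mm) then three rotations (radians), one row per volume.
#'
#' @param path TSV file path.
#' @return A tibble with columns `trans_x, trans_y, trans_z, rot_x, rot_y,
#'   rot_z`.
#' @export
read_motion <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(ncol(tbl) >= 6)
  tbl <- tbl[, 1:6]
  names(tbl) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tbl
}

#' @rdname read_motion
#' @param motion motion tibble/matrix with 6 columns.
#' @export
write_motion <- function(motion, path) {
  motion <- as.data.frame(motion)
  names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  readr::write_tsv(motion, path)
  invisible(path)
}
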