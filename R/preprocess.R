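#' Framewise displacement (Power convention)
#'
#' FD at volume i is the sum of absolute backward differences of the three
#' translations (mm) plus `head_radius` times the sum of absolute differences
#' of the three rotations (radians), i.e. rotations are converted to arc
#' displacement on a sphere of the given radius. FD of the first volume is 0.
#'
#' Rotation columns are expected in radians; traces whose rotations exceed
#' 2*pi in magnitude almost certainly carry degrees and are rejected loudly.
#'
#' @param motion matrix/data frame with 6 columns (3 translations mm, 3
#'   rotations rad), one row per volume; >= 2 volumes.
#' @param head_radius sphere radius in mm for the rotation conversion
#'   (default 50).
#' @return Numeric vector of per-volume FD in mm.
#' @export
compute_fd_power <- function(motion, head_radius = 50) {
  m <- as.matrix(as.data.frame(motion))
  stopifnot(ncol(m) == 6)
  if (nrow(m) < 2) stop("motion trace must have at least 2 volumes", call. = FALSE)
  if (max(abs(m[, 4:6])) > 2 * pi) {
    stop("rotation columns exceed 2*pi; are they in degrees? radians expected",
         call. = FALSE)
  }
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Censor high-motion volumes and their neighbours
#'
#' For every volume whose FD exceeds the threshold, that volume plus
#' `n_before` preceding and `n_after` following volumes (clipped to the run
#' bounds) are marked censored. Existing censor flags are preserved: scrubbing
#' only ever adds censoring, so it is monotone in the threshold. Data values
#' are untouched; removal happens when correlations are computed.
#'
#' @param series a [bold_series()].
#' @param fd per-volume FD (mm), length equal to the number of volumes.
#' @param fd_threshold censoring threshold in mm (default 0.5).
#' @param n_before,n_after neighbour volumes to censor (defaults 1 and 2).
#' @return The series with updated censor flags.
#' @export
scrub <- function(series, fd, fd_threshold = 0.5, n_before = 1, n_after = 2) {
  stopifnot(inherits(series, "bold_series"), fd_threshold > 0,
            n_before >= 0, n_after >= 0)
  nt <- n_volumes(series)
  if (length(fd) != nt) stop("fd length must equal the volume count", call. = FALSE)
  bad <- which(fd > fd_threshold)
  drop <- unique(unlist(lapply(bad, function(i) {
    max(1L, i - n_before):min(nt, i + n_after)
  })))
  series$censor[drop] <- FALSE
  if (!any(series$censor)) warning("all volumes censored")
  record_step(series, "scrub")
}

#' Regress nuisance signals out of every voxel
#'
#' Fits ordinary least squares of each voxel's time series on an intercept
#' plus the given regressors, using retained (non-censored) volumes only, and
#' replaces the series with the residuals (computed for all volumes from the
#' retained-volume coefficients, preserving index alignment). With no
#' regressors this demeans the data.
#'
#' @param series a [bold_series()].
#' @param regressors numeric matrix with one row per volume (columns e.g.
#'   motion parameters, tissue signals); may have zero columns.
#' @return The series with residualized data.
#' @export
regress_nuisance <- function(series, regressors = NULL) {
  stopifnot(inherits(series, "bold_series"))
  nt <- n_volumes(series)
  if (is.null(regressors)) regressors <- matrix(numeric(0), nrow = nt, ncol = 0)
  regressors <- as.matrix(regressors)
  stopifnot(nrow(regressors) == nt)
  X <- cbind(intercept = 1, regressors)
  keep <- series$censor
  qr_X <- qr(X[keep, , drop = FALSE])
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    if (is.null(dropped)) dropped <- qr_X$pivot[(qr_X$rank + 1):ncol(X)]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_X, series$data[keep, , drop = FALSE])
  series$data <- series$data - X %*% beta
  record_step(series, "regress_nuisance")
}

#' Motion regressor expansion
#'
#' The six rigid-body parameters plus (optionally) their element-wise squares
#' -- the standard quadratic expansion of the motion design.
#'
#' @param motion 6-column motion trace.
#' @param include_squares add squared terms (default TRUE).
#' @return Numeric matrix with 6 or 12 columns.
#' @export
motion_regressors <- function(motion, include_squares = TRUE) {
  m <- as.matrix(as.data.frame(motion))
  stopifnot(ncol(m) == 6)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (include_squares) {
    sq <- m^2
    colnames(sq) <- paste0(colnames(m), "_sq")
    m <- cbind(m, sq)
  }
  m
}

#' Mean signal within a tissue mask
#'
#' @param series a [bold_series()].
#' @param mask a non-empty [brain_mask()] on the same grid.
#' @return Per-volume unweighted mean over mask voxels.
#' @export
extract_tissue_signal <- function(series, mask) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "brain_mask"))
  if (!same_grid(series$grid, mask$grid)) stop("mask grid mismatch", call. = FALSE)
  idx <- mask_indices(mask)
  if (!length(idx)) stop("tissue mask is empty", call. = FALSE)
  rowMeans(series$data[, idx, drop = FALSE])
}

# ideal (frequency-mask) filter of a volumes x voxels matrix
ideal_bandpass_matrix <- function(x, tr, low, high) {
  nt <- nrow(x)
  # linear detrend first so edge trends do not leak across bins
  t_idx <- seq_len(nt)
  X <- cbind(1, t_idx)
  x <- x - X %*% qr.coef(qr(X), x)
  k <- 0:(nt - 1)
  freq <- pmin(k, nt - k) / (nt * tr)
  keep <- freq >= low & freq <= high
  keep[1] <- FALSE  # DC always removed
  F <- stats::mvfft(x)
  F[!keep, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / nt
}

#' Bandpass filter a BOLD series
#'
#' Ideal (frequency-domain mask) bandpass after linear detrending, applied
#' voxelwise to the full run. The contract is stated in power terms: a pure
#' in-band sinusoid retains >= 90% of its variance; sinusoids at half the low
#' edge or twice the high edge retain <= 10%.
#'
#' @param series a [bold_series()].
#' @param low,high passband edges in Hz (defaults 0.01 and 0.1); must satisfy
#'   0 < low < high < Nyquist = 1 / (2 TR).
#' @return The filtered series.
#' @export
bandpass <- function(series, low = 0.01, high = 0.1) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr)
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf("invalid band [%g, %g] Hz for TR %g s (Nyquist %g Hz)",
                 low, high, series$tr, nyq), call. = FALSE)
  }
  series$data <- ideal_bandpass_matrix(series$data, series$tr, low, high)
  record_step(series, "bandpass")
}

#' Full per-subject denoising pipeline
#'
#' Applies, in this fixed order: nuisance regression (motion parameters and
#' their squares, CSF and white-matter mean signals), bandpass filtering, and
#' FD-based scrubbing. Scrubbing is last only in the sense that it sets
#' censor flags; the flags then gate every downstream correlation. The order
#' is recorded in `steps` and re-running with identical inputs is
#' bit-reproducible. No spatial smoothing is applied anywhere.
#'
#' @param series a [bold_series()].
#' @param motion 6-column motion trace (translations mm, rotations rad).
#' @param csf_mask,wm_mask tissue masks for mean-signal regressors; either may
#'   be NULL to skip.
#' @param low,high passband in Hz.
#' @param fd_threshold,n_before,n_after scrubbing parameters (see [scrub()]).
#' @param include_motion_squares include squared motion regressors.
#' @param head_radius mm, for [compute_fd_power()].
#' @return The preprocessed series with censor flags set.
#' @export
preprocess_bold <- function(series, motion, csf_mask = NULL, wm_mask = NULL,
                            low = 0.01, high = 0.1,
                            fd_threshold = 0.5, n_before = 1, n_after = 2,
                            include_motion_squares = TRUE, head_radius = 50) {
  reg <- motion_regressors(motion, include_squares = include_motion_squares)
  if (!is.null(csf_mask)) reg <- cbind(reg, csf = extract_tissue_signal(series, csf_mask))
  if (!is.null(wm_mask)) reg <- cbind(reg, wm = extract_tissue_signal(series, wm_mask))
  series <- regress_nuisance(series, reg)
  series <- bandpass(series, low, high)
  fd <- compute_fd_power(motion, head_radius = head_radius)
  scrub(series, fd, fd_threshold = fd_threshold,
        n_before = n_before, n_after = n_after)
}
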