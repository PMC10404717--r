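#' Select the K strongest DLPFC voxels in one hemisphere
#'
#' Ranks defined target-map values within the hemisphere part of the DLPFC
#' mask, descending; ties at the K-th rank are broken by ascending linear
#' voxel index so the selection is deterministic. If fewer than `k` defined
#' voxels exist, all are returned with a warning.
#'
#' @param map a `target_map`.
#' @param dlpfc DLPFC [brain_mask()] on the same grid (user-supplied; the
#'   package does not construct it).
#' @param hemisphere `"left"` or `"right"` (MNI x < 0 / x > 0).
#' @param k number of voxels to select (default 100).
#' @return A `target_set`: tibble with 0-based voxel indices `i, j, k`, MNI
#'   `x, y, z`, and `value`, ordered strongest first; attributes `hemisphere`,
#'   `mean_connectivity`, `peak` (MNI of the argmax) and `linear_index`.
#' @export
select_top_k <- function(map, dlpfc, hemisphere = c("left", "right"), k = 100) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(map, "voxel_map"), inherits(dlpfc, "brain_mask"), k >= 1)
  if (!same_grid(map$grid, dlpfc$grid)) stop("mask grid mismatch", call. = FALSE)
  hemi <- split_hemispheres(dlpfc)[[hemisphere]]
  idx <- mask_indices(hemi)
  if (!length(idx)) stop("hemisphere DLPFC mask is empty", call. = FALSE)
  vals <- map$values[idx]
  ok <- !is.na(vals)
  idx <- idx[ok]; vals <- vals[ok]
  if (!length(idx)) stop("target map undefined over the whole hemisphere mask",
                         call. = FALSE)
  if (length(idx) < k) {
    warning(sprintf("only %d defined voxels available for k = %d",
                    length(idx), k))
  }
  ord <- order(-vals, idx)
  take <- ord[seq_len(min(k, length(idx)))]
  sel <- idx[take]; v <- vals[take]
  vox <- linear_to_voxel(sel, map$grid)
  mm <- cbind(vox, 1) %*% t(map$grid$affine)
  out <- tibble::tibble(
    i = vox[, 1], j = vox[, 2], k = vox[, 3],
    x = mm[, 1], y = mm[, 2], z = mm[, 3], value = v
  )
  structure(out,
            class = c("target_set", class(out)),
            hemisphere = hemisphere, k = as.integer(k),
            mean_connectivity = mean(v),
            peak = c(x = mm[1, 1], y = mm[1, 2], z = mm[1, 3]),
            linear_index = sel)
}

#' Target connectivity strength
#'
#' Mean target-map value over each hemisphere's selected voxels; with
#' `pool = TRUE` the two hemisphere means are averaged into a single pooled
#' strength (the hemispheres being strongly intercorrelated in practice).
#'
#' @param map the `target_map` the sets came from.
#' @param left,right `target_set` objects from [select_top_k()].
#' @param pool return the pooled mean of the two hemisphere values.
#' @return A tibble with columns `hemisphere` and `strength` (rows left,
#'   right, and optionally pooled).
#' @export
target_connectivity_strength <- function(map, left, right, pool = TRUE) {
  stopifnot(inherits(map, "voxel_map"))
  one <- function(set) {
    lin <- attr(set, "linear_index")
    if (!length(lin)) stop("empty target set", call. = FALSE)
    mean(map$values[lin])
  }
  l <- one(left); r <- one(right)
  out <- tibble::tibble(hemisphere = c("left", "right"), strength = c(l, r))
  if (pool) out <- dplyr::bind_rows(
    out, tibble::tibble(hemisphere = "pooled", strength = (l + r) / 2))
  out
}

#' Percentage overlap map of individual targets
#'
#' Binarizes each subject's target set, sums across subjects, divides by the
#' subject count and multiplies by 100, yielding the percentage of subjects
#' selecting each voxel.
#'
#' @param sets list of `target_set` objects on a shared grid (one per
#'   subject; pass e.g. all left-hemisphere sets).
#' @param grid the shared [volume_grid()].
#' @return An `overlap_map` (values in [0, 100]) with attributes
#'   `n_subjects`, `argmax_mni` and `argmax_pct`.
#' @export
group_overlap_map <- function(sets, grid) {
  stopifnot(length(sets) >= 1, inherits(grid, "volume_grid"))
  counts <- numeric(n_voxels(grid))
  for (s in sets) {
    lin <- attr(s, "linear_index")
    if (is.null(lin)) stop("set lacks voxel indices", call. = FALSE)
    if (max(lin) > n_voxels(grid)) stop("target set grid mismatch", call. = FALSE)
    counts[lin] <- counts[lin] + 1
  }
  pct <- 100 * counts / length(sets)
  amax <- which.max(pct)
  m <- new_voxel_map(pct, grid, "overlap_map", n_subjects = length(sets))
  m$argmax_mni <- voxel_to_mni(linear_to_voxel(amax, grid)[1, ], grid)
  m$argmax_pct <- pct[amax]
  m
}

#' Pairwise distances between individual target-map peaks
#'
#' For each subject, the strongest defined voxel within the mask is found and
#' converted to MNI mm; all pairwise Euclidean distances are returned with
#' their mean and SD.
#'
#' @param maps list of `target_map` objects (>= 2 subjects), shared grid.
#' @param mask hemisphere DLPFC [brain_mask()].
#' @return List with `peaks` (tibble subject, x, y, z), `distances` (tibble
#'   subject_a, subject_b, distance_mm), `mean`, `sd`.
#' @export
peak_distances <- function(maps, mask) {
  stopifnot(length(maps) >= 2, inherits(mask, "brain_mask"))
  idx <- mask_indices(mask)
  peaks <- t(vapply(seq_along(maps), function(s) {
    m <- maps[[s]]
    if (!same_grid(m$grid, mask$grid)) stop("map grid mismatch", call. = FALSE)
    v <- m$values[idx]
    if (all(is.na(v))) stop("target map undefined over the mask for subject ",
                            s, call. = FALSE)
    best <- idx[order(-v, idx)[1]]
    voxel_to_mni(linear_to_voxel(best, m$grid)[1, ], m$grid)
  }, numeric(3)))
  pairs <- utils::combn(length(maps), 2)
  d <- sqrt(rowSums((peaks[pairs[1, ], , drop = FALSE] -
                     peaks[pairs[2, ], , drop = FALSE])^2))
  list(
    peaks = tibble::tibble(subject = seq_along(maps),
                           x = peaks[, 1], y = peaks[, 2], z = peaks[, 3]),
    distances = tibble::tibble(subject_a = pairs[1, ], subject_b = pairs[2, ],
                               distance_mm = d),
    mean = mean(d), sd = stats::sd(d)
  )
}

#' Group-mean connectivity at stimulated coordinates
#'
#' Averages the supplied maps voxelwise, then reads the group-mean value at
#' the voxel nearest each MNI coordinate (no interpolation).
#'
#' @param group_maps list of `target_map` objects on a shared grid.
#' @param coords matrix/data frame of MNI mm coordinates (columns x, y, z).
#' @return Tibble with `x, y, z, value`. Out-of-bounds coordinates raise an
#'   error naming the coordinate.
#' @export
extract_at_coordinates <- function(group_maps, coords) {
  stopifnot(length(group_maps) >= 1)
  grid <- group_maps[[1]]$grid
  vals <- rowMeans(vapply(group_maps, function(m) {
    if (!same_grid(m$grid, grid)) stop("map grid mismatch", call. = FALSE)
    m$values
  }, numeric(n_voxels(grid))))
  cm <- as.matrix(as.data.frame(coords)[, 1:3])
  v <- vapply(seq_len(nrow(cm)), function(i) {
    vox <- mni_to_voxel(cm[i, ], grid)
    vals[voxel_linear_index(vox, grid)]
  }, numeric(1))
  tibble::tibble(x = cm[, 1], y = cm[, 2], z = cm[, 3], value = v)
}

#' Correlate target connectivity strength with clinical outcome
#'
#' Plain Pearson correlation of per-subject strengths with outcome, plus
#' (optionally) the partial correlation adjusted for covariates: both
#' variables are residualized on an intercept plus the covariate design
#' (categorical covariates one-hot encoded via `model.matrix`), the residuals
#' are correlated, and the p-value uses a t distribution with
#' n - 2 - q degrees of freedom (q = number of covariate columns).
#'
#' @param strengths numeric per-subject connectivity strengths.
#' @param outcome numeric per-subject outcome (e.g. BDI % change).
#' @param covariates data frame of covariates (e.g. device, protocol,
#'   n_sessions), one row per subject; NULL for unadjusted only.
#' @return Tibble with rows `pearson` and (if covariates given) `partial`:
#'   columns `method, r, statistic, df, p_value, n`.
#' @export
adjusted_outcome_correlation <- function(strengths, outcome, covariates = NULL) {
  x <- as.numeric(strengths); y <- as.numeric(outcome)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant variable: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  out <- tibble::tibble(method = "pearson", r = unname(ct$estimate),
                        statistic = unname(ct$statistic),
                        df = unname(ct$parameter), p_value = ct$p.value, n = n)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    X <- stats::model.matrix(~ ., data = covariates)
    q <- ncol(X) - 1L
    if (n < q + 4) stop("too few subjects for partial correlation", call. = FALSE)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design", call. = FALSE)
    rx <- stats::lm.fit(X, x)$residuals
    ry <- stats::lm.fit(X, y)$residuals
    if (stats::sd(rx) < 1e-10 * stats::sd(x) || stats::sd(ry) < 1e-10 * stats::sd(y)) {
      stop("variable fully explained by covariates: partial correlation undefined",
           call. = FALSE)
    }
    r <- stats::cor(rx, ry)
    df <- n - 2L - q
    tstat <- r * sqrt(df / (1 - r^2))
    out <- dplyr::bind_rows(out, tibble::tibble(
      method = "partial", r = r, statistic = tstat, df = df,
      p_value = 2 * stats::pt(-abs(tstat), df), n = n))
  }
  out
}
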