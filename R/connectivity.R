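#' Mean seed time course over retained volumes
#'
#' @param series a [bold_series()].
#' @param seed a non-empty [brain_mask()] on the same grid.
#' @return Numeric vector over retained (non-censored) volumes only.
#' @export
seed_timecourse <- function(series, seed) {
  stopifnot(inherits(series, "bold_series"), inherits(seed, "brain_mask"))
  if (!same_grid(series$grid, seed$grid)) stop("seed grid mismatch", call. = FALSE)
  idx <- mask_indices(seed)
  if (!length(idx)) stop("seed mask is empty", call. = FALSE)
  if (!any(series$censor)) stop("all volumes are censored", call. = FALSE)
  rowMeans(series$data[series$censor, idx, drop = FALSE])
}

new_voxel_map <- function(values, grid, class, ...) {
  stopifnot(length(values) == n_voxels(grid))
  structure(list(values = as.numeric(values), grid = grid, ...),
            class = c(class, "voxel_map"))
}

#' @export
print.voxel_map <- function(x, ...) {
  def <- sum(!is.na(x$values))
  cat("<", class(x)[1], "> ", def, " defined voxels",
      if (!is.null(x$seed_name)) paste0(", seed ", x$seed_name),
      "; range [", paste(signif(range(x$values, na.rm = TRUE), 3),
                         collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Voxelwise seed connectivity map
#'
#' Pearson correlation of the mean seed time course with every voxel's time
#' series, over retained volumes only. Voxels with zero variance over the
#' retained volumes are flagged undefined (NA), never silently set to 0.
#'
#' @inheritParams seed_timecourse
#' @param seed_name label stored on the map.
#' @return A `connectivity_map` (grid, per-voxel r in [-1, 1] or NA,
#'   `seed_name`, `n_volumes_used`).
#' @export
seed_connectivity_map <- function(series, seed, seed_name = "seed") {
  tc <- seed_timecourse(series, seed)
  if (sum(series$censor) < 3) stop("fewer than 3 retained volumes", call. = FALSE)
  if (stats::sd(tc) == 0) stop("seed time course has zero variance", call. = FALSE)
  Y <- series$data[series$censor, , drop = FALSE]
  n <- nrow(Y)
  tc_c <- tc - mean(tc)
  Yc <- sweep(Y, 2, colMeans(Y))
  sy <- sqrt(colSums(Yc^2))
  r <- as.vector(crossprod(Yc, tc_c)) / (sy * sqrt(sum(tc_c^2)))
  r[sy == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  new_voxel_map(r, series$grid, "connectivity_map",
                seed_name = seed_name, n_volumes_used = n)
}

#' Combine seed connectivity maps into a signed-average target map
#'
#' The core network model target map: each seed's connectivity map is
#' multiplied by its sign (+1 regulatory, -1 regulated) and the signed maps
#' are averaged voxelwise. The sign reversal keeps positively and negatively
#' connected seeds from cancelling. No Fisher transform is applied before
#' averaging by default; `average = "z"` averages atanh-transformed maps and
#' back-transforms, for methods comparison.
#'
#' @param maps list of `connectivity_map` objects on a shared grid.
#' @param signs numeric vector of +1/-1, one per map.
#' @param average "r" (default: plain average of signed r) or "z"
#'   (Fisher-Z-space average).
#' @return A `target_map`; a voxel is undefined (NA) if any component map is
#'   undefined there.
#' @export
combine_maps <- function(maps, signs, average = c("r", "z")) {
  average <- match.arg(average)
  stopifnot(length(maps) == length(signs), all(signs %in% c(-1, 1)))
  grid <- maps[[1]]$grid
  for (m in maps) if (!same_grid(m$grid, grid)) stop("map grid mismatch", call. = FALSE)
  vals <- vapply(seq_along(maps), function(k) {
    v <- signs[k] * maps[[k]]$values
    if (average == "z") atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, v))) else v
  }, numeric(n_voxels(grid)))
  avg <- rowMeans(vals)  # NA propagates: undefined component -> undefined voxel
  if (average == "z") avg <- tanh(avg)
  new_voxel_map(avg, grid, "target_map",
                seed_names = vapply(maps, function(m) m$seed_name %||% "", ""),
                signs = signs)
}

#' Core-network-model target map from a BOLD series
#'
#' Runs [seed_connectivity_map()] for every seed and combines the maps with
#' [combine_maps()]. Restricting `seeds` to the sgACC rows reproduces the
#' single-seed comparison model as a special case of the same code path.
#'
#' @param series a preprocessed [bold_series()].
#' @param seeds a `cnm_seed_set` tibble (default [cnm_seeds()]).
#' @param seed_masks optional named list of exact seed masks overriding the
#'   sphere construction (see [build_seed_masks()]).
#' @param average see [combine_maps()].
#' @return A `target_map`.
#' @export
cnm_target_map <- function(series, seeds = cnm_seeds(), seed_masks = NULL,
                           average = c("r", "z")) {
  masks <- build_seed_masks(seeds, series$grid, masks = seed_masks)
  maps <- lapply(seq_along(masks), function(k) {
    seed_connectivity_map(series, masks[[k]], seed_name = names(masks)[k])
  })
  combine_maps(maps, seeds$sign, average = average)
}

#' Write any voxel map (connectivity, target, overlap) as NIfTI
#'
#' @param map a `voxel_map` object.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  arr <- array(map$values, dim = map$grid$shape)
  RNifti::writeNifti(nifti_with_affine(arr, map$grid), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  g <- grid_from_nifti(img)
  new_voxel_map(as.numeric(img), g, "target_map")
}
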