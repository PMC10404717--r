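#' Seed specification tables
#'
#' A seed set is an ordered tibble with one row per seed: `name`, peak MNI
#' coordinate (`x`, `y`, `z` mm), `sign` (+1 for regulatory seeds whose
#' connectivity enters the target map as-is, -1 for regulated seeds whose
#' connectivity is sign-reversed before averaging) and sphere `radius` (mm).
#' A `provenance` column is optional free text.
#'
#' @param name seed label.
#' @param x,y,z MNI peak coordinate in mm.
#' @param sign +1 or -1.
#' @param radius sphere radius in mm, >= 0.
#' @param provenance optional free text.
#' @return A one-row tibble (class `cnm_seed_set` on top of `tbl_df`).
#' @export
seed_spec <- function(name, x, y, z, sign, radius = 6, provenance = NA_character_) {
  stopifnot(sign %in% c(-1, 1), radius >= 0)
  new_seed_set(tibble::tibble(
    name = as.character(name), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), sign = as.numeric(sign), radius = as.numeric(radius),
    provenance = as.character(provenance)
  ))
}

new_seed_set <- function(tbl) {
  stopifnot(all(c("name", "x", "y", "z", "sign", "radius") %in% names(tbl)))
  if (anyDuplicated(tbl$name)) stop("seed names must be unique", call. = FALSE)
  if (!all(tbl$sign %in% c(-1, 1))) stop("seed sign must be +1 or -1", call. = FALSE)
  if (any(tbl$radius < 0)) stop("seed radius must be >= 0", call. = FALSE)
  class(tbl) <- unique(c("cnm_seed_set", class(tbl)))
  tbl
}

#' The default eight-seed core network model
#'
#' Peak MNI coordinates of the eight seeds: bilateral anterior insula and
#' dorsal anterior cingulate (regulatory, sign +1) and bilateral amygdala and
#' subgenual cingulate (regulated, sign -1). The coordinates are the
#' major-depression association peaks of the published model; the association
#' Z-scores and DLPFC connectivity r of each seed are carried in `provenance`.
#' The actual cluster shapes are approximated as spheres of the given radius;
#' exact user-supplied masks can be substituted via [build_seed_masks()].
#'
#' @param radius sphere radius in mm (default 6).
#' @return A `cnm_seed_set` tibble with 8 rows.
#' @examples
#' cnm_seeds()
#' @export
cnm_seeds <- function(radius = 6) {
  stopifnot(radius >= 0)
  tbl <- tibble::tribble(
    ~name,           ~x,  ~y,  ~z, ~sign, ~provenance,
    "L_ant_insula", -34,  20,   4,     1, "Z=11.7; r(DLPFC)=0.39",
    "R_ant_insula",  36,  20,  -4,     1, "Z=11.7; r(DLPFC)=0.34",
    "L_dACC",        -2,  24,  40,     1, "Z=9; r(DLPFC)=0.34",
    "R_dACC",         2,  20,  36,     1, "Z=14.9; r(DLPFC)=0.44",
    "L_amygdala",   -22,  -6, -16,    -1, "Z=22.6; r(DLPFC)=-0.18",
    "R_amygdala",    22,  -2, -16,    -1, "Z=17.9; r(DLPFC)=-0.14",
    "L_sgACC",       -6,  16, -10,    -1, "r(DLPFC)=-0.15",
    "R_sgACC",        6,  16, -10,    -1, "r(DLPFC)=-0.16"
  )
  tbl$radius <- as.numeric(radius)
  new_seed_set(tbl[, c("name", "x", "y", "z", "sign", "radius", "provenance")])
}

#' Build a spherical seed mask around a peak coordinate
#'
#' The mask contains every voxel whose centre lies within `radius` mm
#' (Euclidean, in mm space through the affine) of the peak; the voxel nearest
#' the peak is always included, so a zero radius yields exactly one voxel.
#'
#' @param spec a one-row seed table (see [seed_spec()]), or anything with
#'   `x`, `y`, `z`, `radius` fields.
#' @param grid a [volume_grid()].
#' @return A [brain_mask()].
#' @export
build_sphere_seed <- function(spec, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  peak <- c(spec$x[1], spec$y[1], spec$z[1])
  peak_vox <- mni_to_voxel(peak, grid)  # errors if out of bounds
  mm <- grid_voxel_mm(grid)
  d2 <- (mm[, 1] - peak[1])^2 + (mm[, 2] - peak[2])^2 + (mm[, 3] - peak[3])^2
  sel <- d2 <= spec$radius[1]^2
  sel[voxel_linear_index(peak_vox, grid)] <- TRUE
  brain_mask(grid, sel)
}

#' Build one mask per seed of a seed set
#'
#' @param seeds a `cnm_seed_set` tibble.
#' @param grid a [volume_grid()].
#' @param masks optional named list of pre-built [brain_mask()] objects that
#'   override the sphere construction for the matching seed names (the escape
#'   hatch for exact cluster masks).
#' @return Named list of [brain_mask()] objects, in seed-table order.
#' @export
build_seed_masks <- function(seeds, grid, masks = NULL) {
  out <- lapply(seq_len(nrow(seeds)), function(i) {
    nm <- seeds$name[i]
    if (!is.null(masks) && nm %in% names(masks)) {
      m <- masks[[nm]]
      stopifnot(inherits(m, "brain_mask"))
      if (!same_grid(m$grid, grid)) stop("seed mask grid mismatch for ", nm)
      m
    } else {
      build_sphere_seed(seeds[i, ], grid)
    }
  })
  names(out) <- seeds$name
  out
}

#' Read / write seed tables
#'
#' Seed tables are TSV files with columns `name, x, y, z, sign, radius`
#' (plus optional `provenance`), or the equivalent JSON array of records.
#'
#' @param path file path; format chosen by extension (`.json` vs TSV).
#' @return `read_seed_table()` returns a `cnm_seed_set` tibble.
#' @export
read_seed_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tbl <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
  }
  if (!"provenance" %in% names(tbl)) tbl$provenance <- NA_character_
  new_seed_set(tbl[, c("name", "x", "y", "z", "sign", "radius", "provenance")])
}

#' @rdname read_seed_table
#' @param seeds a `cnm_seed_set` tibble.
#' @export
write_seed_table <- function(seeds, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(seeds, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    readr::write_tsv(seeds, path)
  }
  invisible(path)
}
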