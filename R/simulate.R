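#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the core network model
#' assumes: one band-limited latent "regulation" signal that loads positively
#' on the regulatory seeds and the planted (bilateral) DLPFC target clusters
#' and negatively on the regulated seeds, plus white Gaussian voxel noise and
#' motion traces with configurable FD spikes. The grid is a deliberately
#' small MNI-style lattice so full-pipeline runs stay fast, with its own
#' scaled-down seed layout (4 regulatory +1, 4 regulated -1 seeds, mirroring
#' the eight-seed model's sign structure).
#'
#' @param grid a [volume_grid()]; default 20 x 24 x 20 voxels at 3 mm.
#' @param n_volumes volumes per run (default 1000, a full story-length run).
#' @param tr repetition time in seconds (default 1.7, so 1000 volumes span
#'   ~28 minutes and a 125-volume segment is ~3.5 minutes).
#' @param seeds scaled-down `cnm_seed_set` tibble (default [sim_seeds()]).
#' @param target_center MNI mm centre of the planted left-hemisphere target
#'   cluster; the right cluster is its x-mirror.
#' @param target_radius cluster radius in mm.
#' @param jitter_sd per-subject, per-hemisphere SD (mm) of the Gaussian
#'   jitter applied to the planted centres (default 6).
#' @param snr ratio of latent-signal loading to noise SD inside clusters
#'   (default 0.35, giving expected in-cluster target-map values near 0.3,
#'   the magnitude of target connectivity strengths in real data).
#' @param n_subjects cohort size (default 29).
#' @param band passband of the latent signal in Hz.
#' @param motion_spike_times volumes (1-based) at which a 1-volume motion
#'   spike is inserted; default ~30% and ~70% through the run.
#' @param motion_spike_mm spike amplitude (x translation step, mm).
#' @param stim_jitter_sd SD (mm) of the offset of each subject's "stimulated"
#'   coordinate from their true left target centre.
#' @param outcome_slope,outcome_noise_sd linear model linking ground-truth
#'   connectivity at the stimulated voxel to the simulated outcome
#'   (BDI-%-change-like scale).
#' @param rng_seed integer; makes the whole cohort bit-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid = volume_grid(c(20, 24, 20),
                                          mni_affine(3, c(-30, -36, -30))),
                       n_volumes = 1000, tr = 1.7,
                       seeds = sim_seeds(),
                       target_center = c(-21, 24, 12), target_radius = 6,
                       jitter_sd = 6, snr = 0.35, n_subjects = 29,
                       band = c(0.01, 0.1),
                       motion_spike_times = round(c(0.3, 0.7) * n_volumes),
                       motion_spike_mm = 1,
                       stim_jitter_sd = 6,
                       outcome_slope = 100, outcome_noise_sd = 10,
                       rng_seed = 42) {
  stopifnot(snr >= 0, jitter_sd >= 0, n_volumes >= 2, tr > 0,
            target_radius >= 0, n_subjects >= 1)
  structure(list(
    grid = grid, n_volumes = as.integer(n_volumes), tr = tr, seeds = seeds,
    target_center = target_center, target_radius = target_radius,
    jitter_sd = jitter_sd, snr = snr, n_subjects = as.integer(n_subjects),
    band = band, motion_spike_times = motion_spike_times,
    motion_spike_mm = motion_spike_mm, stim_jitter_sd = stim_jitter_sd,
    outcome_slope = outcome_slope, outcome_noise_sd = outcome_noise_sd,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

#' Scaled-down seed layout for the synthetic grid
#'
#' Eight spherical seeds inside the small default grid, mirroring the real
#' model's structure: bilateral insula-like and dACC-like regulatory seeds
#' (sign +1) and bilateral amygdala-like and sgACC-like regulated seeds
#' (sign -1).
#'
#' @param radius sphere radius in mm (default 6).
#' @return A `cnm_seed_set` tibble with 8 rows.
#' @export
sim_seeds <- function(radius = 6) {
  tbl <- tibble::tribble(
    ~name,             ~x,  ~y,  ~z, ~sign,
    "L_insula_like", -21,   9,   0,     1,
    "R_insula_like",  21,   9,   0,     1,
    "L_dacc_like",    -3,  15,  18,     1,
    "R_dacc_like",     3,  15,  18,     1,
    "L_amygdala_like", -18, -9, -12,   -1,
    "R_amygdala_like",  18, -9, -12,   -1,
    "L_sgacc_like",   -6,   9, -18,    -1,
    "R_sgacc_like",    6,   9, -18,    -1
  )
  tbl$radius <- as.numeric(radius)
  tbl$provenance <- "synthetic layout"
  new_seed_set(tbl[, c("name", "x", "y", "z", "sign", "radius", "provenance")])
}

#' Stand-in DLPFC mask for the synthetic grid
#'
#' A bilateral prefrontal-like region (|x| >= 9 mm, y >= 18 mm, z >= 0 mm)
#' containing the planted target clusters and disjoint from every synthetic
#' seed. Labelled synthetic: it stands in for the user-supplied DLPFC mask
#' that real analyses require.
#'
#' @param grid a [volume_grid()].
#' @return A [brain_mask()].
#' @export
sim_dlpfc_mask <- function(grid) {
  mm <- grid_voxel_mm(grid)
  brain_mask(grid, abs(mm[, 1]) >= 9 & mm[, 2] >= 18 & mm[, 3] >= 0)
}

#' Band-limited unit-variance latent signal
#'
#' White Gaussian noise passed through the ideal bandpass used elsewhere in
#' the package, then standardized to zero mean and unit variance. All
#' spectral mass lies inside the band by construction.
#'
#' @param n_volumes length of the series.
#' @param tr repetition time (s).
#' @param band passband (Hz), inside the Nyquist limit.
#' @return Numeric vector, mean 0, variance 1.
#' @export
generate_latent <- function(n_volumes, tr, band = c(0.01, 0.1)) {
  nyq <- 1 / (2 * tr)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop("invalid band for this TR", call. = FALSE)
  }
  u <- ideal_bandpass_matrix(matrix(stats::rnorm(n_volumes), ncol = 1),
                             tr, band[1], band[2])[, 1]
  u <- u - mean(u)
  u / stats::sd(u)
}

# per-subject RNG seed, derived from the cohort seed by a documented offset so
# cohorts are stable under subject-count changes
subject_seed <- function(cfg, subject_id) {
  (cfg$rng_seed + 10007L * as.integer(subject_id)) %% .Machine$integer.max
}

# draw a jittered centre, resampling until its sphere centre is in-grid
jitter_center <- function(center, sd_mm, grid, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    cand <- center + stats::rnorm(3, 0, sd_mm)
    ok <- tryCatch({mni_to_voxel(cand, grid); TRUE}, error = function(e) FALSE)
    if (ok) return(cand)
    message("jittered target centre out of grid; resampling")
  }
  center
}

#' Expected generator correlations (closed form)
#'
#' Under the generator, a voxel with latent loading `w_voxel` has series
#' w u + e; the mean over a seed of m voxels each loading `w_seed` has series
#' w_seed u + e'/sqrt(m). Their expected Pearson correlation is
#' w_voxel w_seed / sqrt((w_voxel^2 + 1)(w_seed^2 + 1/m)).
#' `expected_target_value()` averages the signed version over a seed set for
#' a voxel loading `w_voxel`, i.e. the expected target-map value.
#'
#' @param w_voxel,w_seed latent loadings (signed multiples of snr).
#' @param m_seed number of voxels averaged in the seed.
#' @return Expected correlation.
#' @export
expected_seed_voxel_correlation <- function(w_voxel, w_seed, m_seed) {
  (w_voxel * w_seed) / sqrt((w_voxel^2 + 1) * (w_seed^2 + 1 / m_seed))
}

#' @rdname expected_seed_voxel_correlation
#' @param cfg a [sim_config()].
#' @param seed_sizes voxel counts of the seed masks (computed from cfg when
#'   omitted).
#' @export
expected_target_value <- function(w_voxel, cfg, seed_sizes = NULL) {
  if (is.null(seed_sizes)) {
    masks <- build_seed_masks(cfg$seeds, cfg$grid)
    seed_sizes <- vapply(masks, function(m) sum(m$voxels), numeric(1))
  }
  signs <- cfg$seeds$sign
  mean(signs * expected_seed_voxel_correlation(w_voxel, signs * cfg$snr,
                                               seed_sizes))
}

#' Generate one synthetic subject
#'
#' Voxel series are w(v) u(t) + e with e iid N(0, 1): w = +snr inside the
#' regulatory seeds and the subject's jittered bilateral target clusters,
#' -snr inside the regulated seeds, 0 elsewhere. The motion trace is a slow
#' random walk plus the configured 1-volume spikes.
#'
#' @param cfg a [sim_config()].
#' @param subject_id integer subject index (drives the per-subject RNG
#'   stream).
#' @return List with `series` ([bold_series()]), `motion` (tibble), and
#'   `ground_truth` (list: jittered centres, target cluster voxel indices,
#'   latent signal, sparse loading weights).
#' @export
generate_subject <- function(cfg, subject_id = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(subject_seed(cfg, subject_id))
  grid <- cfg$grid
  nv <- n_voxels(grid)

  center_l <- jitter_center(cfg$target_center, cfg$jitter_sd, grid)
  center_r <- jitter_center(cfg$target_center * c(-1, 1, 1), cfg$jitter_sd, grid)
  tgt_l <- build_sphere_seed(
    list(x = center_l[1], y = center_l[2], z = center_l[3],
         radius = cfg$target_radius), grid)
  tgt_r <- build_sphere_seed(
    list(x = center_r[1], y = center_r[2], z = center_r[3],
         radius = cfg$target_radius), grid)

  w <- numeric(nv)
  seed_masks <- build_seed_masks(cfg$seeds, grid)
  for (k in seq_along(seed_masks)) {
    w[mask_indices(seed_masks[[k]])] <- cfg$seeds$sign[k] * cfg$snr
  }
  w[mask_indices(tgt_l)] <- cfg$snr
  w[mask_indices(tgt_r)] <- cfg$snr

  u <- generate_latent(cfg$n_volumes, cfg$tr, cfg$band)
  data <- tcrossprod(u, w) +
    matrix(stats::rnorm(cfg$n_volumes * nv), nrow = cfg$n_volumes)
  series <- bold_series(data, grid, tr = cfg$tr, steps = "simulated")

  steps <- cbind(matrix(stats::rnorm(cfg$n_volumes * 3, 0, 0.02), ncol = 3),
                 matrix(stats::rnorm(cfg$n_volumes * 3, 0, 2e-4), ncol = 3))
  motion <- apply(steps, 2, cumsum)
  spikes <- cfg$motion_spike_times
  spikes <- spikes[spikes >= 1 & spikes <= cfg$n_volumes]
  motion[spikes, 1] <- motion[spikes, 1] + cfg$motion_spike_mm
  motion <- tibble::as_tibble(as.data.frame(motion))
  names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

  nz <- which(w != 0)
  list(series = series, motion = motion,
       ground_truth = list(
         subject_id = subject_id,
         target_center_left = center_l, target_center_right = center_r,
         target_voxels_left = mask_indices(tgt_l),
         target_voxels_right = mask_indices(tgt_r),
         latent = u,
         weight_index = nz, weight_value = w[nz],
         snr = cfg$snr))
}

#' Generate a full synthetic cohort
#'
#' Subjects share the seed layout and differ by target jitter and noise
#' (independent RNG streams derived from the cohort seed). Each subject also
#' receives a "stimulated" coordinate near their true left target centre,
#' covariates (device, protocol, session count), and an outcome simulated as
#' `outcome_slope * true_connectivity + N(0, outcome_noise_sd)`, where
#' true_connectivity is the closed-form expected target-map value at the
#' stimulated voxel.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, per-subject NIfTI series,
#'   motion TSVs, the outcome table, seed table, DLPFC mask and a
#'   ground-truth JSON are written there.
#' @return List with `subjects` (list of [generate_subject()] results),
#'   `outcomes` (tibble: subject, x, y, z, true_connectivity, outcome,
#'   device, protocol, n_sessions), `dlpfc` mask, `seeds`, and `cfg`.
#' @export
generate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) generate_subject(cfg, s))
  masks <- build_seed_masks(cfg$seeds, cfg$grid)
  sizes <- vapply(masks, function(m) sum(m$voxels), numeric(1))
  rho_in <- expected_target_value(cfg$snr, cfg, seed_sizes = sizes)

  set.seed((cfg$rng_seed + 777L) %% .Machine$integer.max)
  rows <- lapply(seq_along(subjects), function(s) {
    gt <- subjects[[s]]$ground_truth
    stim <- jitter_center(gt$target_center_left, cfg$stim_jitter_sd, cfg$grid)
    vox <- voxel_linear_index(mni_to_voxel(stim, cfg$grid), cfg$grid)
    true_conn <- if (vox %in% gt$target_voxels_left) rho_in else 0
    tibble::tibble(subject = s, x = stim[1], y = stim[2], z = stim[3],
                   true_connectivity = true_conn)
  })
  outcomes <- dplyr::bind_rows(rows)
  n <- nrow(outcomes)
  outcomes$device <- sample(c("magstim", "neuronetics"), n, replace = TRUE)
  outcomes$protocol <- sample(c("10Hz", "20Hz"), n, replace = TRUE)
  outcomes$n_sessions <- sample(20:32, n, replace = TRUE)
  outcomes$outcome <- cfg$outcome_slope * outcomes$true_connectivity +
    stats::rnorm(n, 0, cfg$outcome_noise_sd)

  res <- list(subjects = subjects, outcomes = outcomes,
              dlpfc = sim_dlpfc_mask(cfg$grid), seeds = cfg$seeds, cfg = cfg)
  if (!is.null(out_dir)) write_cohort(res, out_dir)
  res
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    write_bold(sub$series, file.path(out_dir, sprintf("sub-%02d_bold.nii.gz", s)))
    write_motion(sub$motion, file.path(out_dir, sprintf("sub-%02d_motion.tsv", s)))
  }
  readr::write_tsv(cohort$outcomes, file.path(out_dir, "outcomes.tsv"))
  write_seed_table(cohort$seeds, file.path(out_dir, "seeds.tsv"))
  write_mask(cohort$dlpfc, file.path(out_dir, "dlpfc_mask_synthetic.nii.gz"))
  gt <- lapply(cohort$subjects, function(sub) {
    g <- sub$ground_truth
    g$latent <- NULL  # bulky; reproducible from the seed
    g
  })
  jsonlite::write_json(
    list(rng_seed = cohort$cfg$rng_seed, snr = cohort$cfg$snr,
         jitter_sd = cohort$cfg$jitter_sd,
         expected_in_cluster_value = expected_target_value(cohort$cfg$snr,
                                                           cohort$cfg),
         subjects = gt),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
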