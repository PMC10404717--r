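#' Split a BOLD run into equal-length contiguous segments
#'
#' Produces floor(n / segment_length) non-overlapping contiguous segments;
#' tail volumes that do not fill a segment are dropped (so 1000 volumes give
#' 8 segments of 125, 4 of 250 or 2 of 500). Each segment carries its slice
#' of the data and censor flags and inherits the preprocessing provenance.
#'
#' @param series a [bold_series()].
#' @param segment_length volumes per segment, >= 1 and <= run length.
#' @return List of [bold_series()] segments.
#' @export
split_segments <- function(series, segment_length) {
  stopifnot(inherits(series, "bold_series"), segment_length >= 1)
  nt <- n_volumes(series)
  if (segment_length > nt) {
    stop("segment_length exceeds the number of volumes", call. = FALSE)
  }
  n_seg <- nt %/% segment_length
  lapply(seq_len(n_seg), function(s) {
    rows <- ((s - 1) * segment_length + 1):(s * segment_length)
    seg <- bold_series(series$data[rows, , drop = FALSE], series$grid,
                       tr = series$tr, censor = series$censor[rows],
                       steps = series$steps)
    record_step(seg, sprintf("segment_%d_of_%d_len_%d", s, n_seg, segment_length))
  })
}

#' Spatial correlation of two maps within a mask
#'
#' Pearson correlation of the two maps' values over the jointly defined
#' voxels of the mask. Symmetric in its arguments and invariant to common
#' positive rescaling.
#'
#' @param map_a,map_b `voxel_map` objects on a shared grid.
#' @param mask analysis [brain_mask()] (e.g. bilateral DLPFC).
#' @return Pearson r.
#' @export
spatial_correlation <- function(map_a, map_b, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!same_grid(map_a$grid, map_b$grid) || !same_grid(map_a$grid, mask$grid)) {
    stop("grid mismatch", call. = FALSE)
  }
  idx <- mask_indices(mask)
  a <- map_a$values[idx]; b <- map_b$values[idx]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 jointly defined voxels in mask", call. = FALSE)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance within mask", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Mean pairwise spatial correlation (r_spat) of segment maps
#'
#' Computes the spatial correlation between all C(n, 2) pairs of target maps
#' from equal-length segments and summarizes them by their arithmetic mean in
#' r space (the default). `average = "z"` instead averages Fisher-Z values and
#' back-transforms, for inference-oriented workflows.
#'
#' @param maps list of >= 2 `target_map` objects from equal-length segments.
#' @param mask analysis mask (bilateral DLPFC).
#' @param average "r" (default) or "z".
#' @return List with `mean` (the r_spat summary) and `pairs` (tibble
#'   segment_a, segment_b, r).
#' @export
rspat <- function(maps, mask, average = c("r", "z")) {
  average <- match.arg(average)
  stopifnot(length(maps) >= 2)
  pr <- utils::combn(length(maps), 2)
  r <- vapply(seq_len(ncol(pr)), function(p) {
    spatial_correlation(maps[[pr[1, p]]], maps[[pr[2, p]]], mask)
  }, numeric(1))
  m <- if (average == "z") tanh(mean(atanh(r))) else mean(r)
  list(mean = m,
       pairs = tibble::tibble(segment_a = pr[1, ], segment_b = pr[2, ], r = r))
}

#' Fisher Z transform and its inverse
#'
#' @param r correlation(s), |r| < 1.
#' @return `fisher_z()` returns atanh(r); `fisher_z_inv()` returns tanh(z).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for Fisher Z", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher Z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Paired t-test on Fisher-Z repeatability values
#'
#' Standard paired t statistic on per-subject Fisher-Z values from two
#' conditions (e.g. full model vs single-seed model), n - 1 degrees of
#' freedom, two-sided p.
#'
#' @param z_a,z_b per-subject Fisher-Z values, equal length >= 2.
#' @return Tibble with `t, df, p_value, mean_diff, n`.
#' @export
paired_rspat_test <- function(z_a, z_b) {
  stopifnot(length(z_a) == length(z_b), length(z_a) >= 2)
  d <- z_a - z_b
  if (all(d == 0)) stop("all paired differences are zero: t undefined", call. = FALSE)
  ht <- stats::t.test(z_a, z_b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_diff = mean(d), n = length(d))
}

#' Fold change of explained variance between two repeatability values
#'
#' Interpreting a spatial correlation r as explaining r^2 of a map's
#' variance, the fold change between conditions is (r_a / r_b)^2.
#'
#' @param r_a,r_b correlations; `r_b` must be nonzero.
#' @return (r_a / r_b)^2.
#' @export
variance_fold <- function(r_a, r_b) {
  if (any(r_b == 0)) stop("r_b must be nonzero", call. = FALSE)
  (r_a / r_b)^2
}

#' Fit the exponential scan-time model of repeatability
#'
#' Fits r_spat(t) = r_spatmax - exp(-t / a) by bounded nonlinear least
#' squares (Levenberg-Marquardt), with r_spatmax constrained to (0, 1] and
#' a > 0. Initialization: r_spatmax0 = max(r) + 0.05 clipped to 1 and
#' a0 = median(t), refined over a small deterministic grid of alternative
#' starts (the bound at r_spatmax = 1 can trap a single start); the
#' lowest-SSE converged fit wins, so fits are reproducible. Non-convergence
#' of every start is reported in `converged`, never as silent garbage.
#'
#' @param t scan times in minutes.
#' @param r observed r_spat values (same length).
#' @return An `rspat_fit` object: list with `r_spatmax`, `a`, `fitted`,
#'   `residuals`, `converged`, `data` (tibble t, r). Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_exponential <- function(t, r) {
  stopifnot(length(t) == length(r))
  if (length(unique(t)) < 2) stop("need >= 2 distinct scan times", call. = FALSE)
  dat <- data.frame(t = as.numeric(t), r = as.numeric(r))
  a0 <- stats::median(dat$t)
  if (a0 <= 0) a0 <- 1
  starts <- expand.grid(rmax = unique(pmin(pmax(c(max(dat$r) + 0.05,
                                                  mean(dat$r) + 0.3, 1), 0.05), 1)),
                        a = a0 * c(0.25, 1, 4))
  fit <- NULL; best_sse <- Inf; last_err <- NULL
  for (s in seq_len(nrow(starts))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(r ~ rmax - exp(-t / a), data = dat,
                        start = as.list(starts[s, ]),
                        lower = c(rmax = 1e-8, a = 1e-8),
                        upper = c(rmax = 1, a = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) e)
    if (inherits(cand, "error")) { last_err <- cand; next }
    sse <- sum(stats::residuals(cand)^2)
    if (sse < best_sse) { best_sse <- sse; fit <- cand }
  }
  if (is.null(fit)) {
    return(structure(list(r_spatmax = NA_real_, a = NA_real_,
                          fitted = rep(NA_real_, nrow(dat)),
                          residuals = rep(NA_real_, nrow(dat)),
                          converged = FALSE,
                          message = if (!is.null(last_err))
                            conditionMessage(last_err) else "no fit",
                          data = tibble::as_tibble(dat)),
                     class = "rspat_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(r_spatmax = unname(cf["rmax"]), a = unname(cf["a"]),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 converged = fit$convInfo$isConv %||% TRUE,
                 message = NULL, data = tibble::as_tibble(dat)),
            class = "rspat_fit")
}

#' @export
print.rspat_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<rspat_fit> did not converge:", x$message %||% "", "\n")
  } else {
    cat(sprintf("<rspat_fit> r_spat(t) = %.4f - exp(-t / %.4f)  [t in minutes]\n",
                x$r_spatmax, x$a))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rspat_fit <- function(x, ...) {
  tibble::tibble(term = c("r_spatmax", "a"),
                 estimate = c(x$r_spatmax, x$a))
}

#' @export
glance.rspat_fit <- function(x, ...) {
  tibble::tibble(r_spatmax = x$r_spatmax, a = x$a,
                 sigma = if (x$converged) sqrt(mean(x$residuals^2)) else NA_real_,
                 n = nrow(x$data), converged = x$converged)
}

#' Full repeatability curve for one subject
#'
#' For each requested segment length: split the run, compute a target map per
#' segment, compute r_spat within the mask, and convert the segment length to
#' scan time (segment_length * TR / 60 minutes, nominal volumes;
#' `effective_time = TRUE` instead uses the mean retained volume count). The
#' exponential model is fitted to the resulting (t, mean r_spat) points when
#' at least two lengths are given.
#'
#' @param series a preprocessed [bold_series()].
#' @param seeds a `cnm_seed_set` tibble.
#' @param mask analysis mask (bilateral DLPFC).
#' @param lengths segment lengths in volumes (default c(125, 250, 500)).
#' @param effective_time use censoring-adjusted scan time.
#' @param seed_masks optional exact seed masks (see [build_seed_masks()]).
#' @return An `rspat_curve`: list with `points` (tibble scan_time_min,
#'   segment_length, n_segments, r_spat_mean, r_spat_sd), `pairs` (per-pair
#'   tibble), and `fit` (an `rspat_fit` or NULL).
#' @export
repeatability_curve <- function(series, seeds = cnm_seeds(), mask,
                                lengths = c(125, 250, 500),
                                effective_time = FALSE, seed_masks = NULL) {
  pts <- list(); allpairs <- list()
  for (len in lengths) {
    segs <- split_segments(series, len)
    maps <- lapply(segs, cnm_target_map, seeds = seeds, seed_masks = seed_masks)
    rs <- rspat(maps, mask)
    t_min <- if (effective_time) {
      mean(vapply(segs, function(s) sum(s$censor), numeric(1))) * series$tr / 60
    } else len * series$tr / 60
    pts[[length(pts) + 1]] <- tibble::tibble(
      scan_time_min = t_min, segment_length = len,
      n_segments = length(segs), r_spat_mean = rs$mean,
      r_spat_sd = stats::sd(rs$pairs$r))
    rs$pairs$segment_length <- len
    allpairs[[length(allpairs) + 1]] <- rs$pairs
  }
  points <- dplyr::arrange(dplyr::bind_rows(pts), .data$scan_time_min)
  fit <- if (nrow(points) >= 2) {
    fit_exponential(points$scan_time_min, points$r_spat_mean)
  } else NULL
  structure(list(points = points, pairs = dplyr::bind_rows(allpairs), fit = fit),
            class = "rspat_curve")
}

#' @export
print.rspat_curve <- function(x, ...) {
  cat("<rspat_curve>\n")
  print(x$points)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
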