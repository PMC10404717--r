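mk_tmap <- function(vals, grid) {
  structure(list(values = vals, grid = grid), class = c("target_map", "voxel_map"))
}

test_that("segment splitting uses the floor rule on contiguous blocks", {
  g <- tiny_grid(c(2, 2, 2))
  long <- bold_series(matrix(rnorm(1000 * 8), 1000, 8), g, tr = 1.7)
  expect_length(split_segments(long, 125), 8)
  expect_length(split_segments(long, 250), 4)
  expect_length(split_segments(long, 500), 2)

  short <- bold_series(matrix(1:56, 7, 8), g, tr = 2,
                       censor = c(TRUE, FALSE, rep(TRUE, 5)))
  segs <- split_segments(short, 3)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$data, short$data[1:3, ])
  expect_equal(segs[[2]]$data, short$data[4:6, ])  # volume 7 dropped
  expect_equal(segs[[1]]$censor, c(TRUE, FALSE, TRUE))
  expect_error(split_segments(short, 8), "exceeds")
})

test_that("spatial correlation over mask voxels matches the textbook formula", {
  g <- tiny_grid(c(5, 5, 5))
  nv <- prod(g$shape)
  set.seed(1)
  a <- mk_tmap(runif(nv), g)
  mask <- random_mask(g, 0.5, seed = 2)

  expect_equal(spatial_correlation(a, a, mask), 1, tolerance = 1e-12)
  neg <- mk_tmap(-a$values, g)
  expect_equal(spatial_correlation(a, neg, mask), -1, tolerance = 1e-12)

  b <- mk_tmap(runif(nv), g)
  idx <- which(as.vector(mask$voxels))
  expect_equal(spatial_correlation(a, b, mask),
               pearson_oracle(a$values[idx], b$values[idx]), tolerance = 1e-12)
  # symmetric and invariant to common positive rescaling
  expect_equal(spatial_correlation(b, a, mask), spatial_correlation(a, b, mask))
  a2 <- mk_tmap(3 * a$values, g); b2 <- mk_tmap(3 * b$values, g)
  expect_equal(spatial_correlation(a2, b2, mask), spatial_correlation(a, b, mask),
               tolerance = 1e-12)

  # NA voxels are excluded pairwise
  a_na <- a; a_na$values[idx[1:3]] <- NA
  expect_equal(spatial_correlation(a_na, b, mask),
               pearson_oracle(a$values[idx[-(1:3)]], b$values[idx[-(1:3)]]),
               tolerance = 1e-12)

  flat <- mk_tmap(rep(1, nv), g)
  expect_error(spatial_correlation(flat, b, mask), "zero variance")
})

test_that("r_spat averages all segment pairs", {
  g <- tiny_grid(c(5, 5, 5))
  nv <- prod(g$shape)
  mask <- random_mask(g, 0.6, seed = 3)
  set.seed(4)
  same <- rep(list(mk_tmap(runif(nv), g)), 3)
  expect_equal(rspat(same, mask)$mean, 1, tolerance = 1e-12)

  maps <- lapply(1:4, function(i) mk_tmap(runif(nv), g))
  rs <- rspat(maps, mask)
  expect_equal(nrow(rs$pairs), 6)
  idx <- which(as.vector(mask$voxels))
  acc <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    acc <- c(acc, pearson_oracle(maps[[i]]$values[idx], maps[[j]]$values[idx]))
  }
  expect_equal(rs$pairs$r, acc, tolerance = 1e-12)
  expect_equal(rs$mean, mean(acc), tolerance = 1e-12)
  # Fisher-Z-space averaging mode
  expect_equal(rspat(maps, mask, average = "z")$mean, tanh(mean(atanh(acc))),
               tolerance = 1e-12)
})

test_that("Fisher Z is atanh with exact round-trip and domain errors", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z_inv(fisher_z(0.73)), 0.73, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("the paired test reproduces the t formula and is antisymmetric", {
  set.seed(5)
  a <- rnorm(10, 1, 0.2)
  b <- a + 0.8 + rnorm(10, 0, 0.01)
  res <- paired_rspat_test(b, a)
  d <- b - a
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 9)
  expect_lt(res$p_value, 1e-6)

  swapped <- paired_rspat_test(a, b)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)

  expect_error(paired_rspat_test(a, a), "zero")
})

test_that("variance fold is the squared correlation ratio", {
  expect_equal(variance_fold(0.4, 0.4), 1)
  expect_equal(variance_fold(0.6, 0.3), 4)
  set.seed(6)
  ra <- runif(10, -1, 1); rb <- runif(10, 0.1, 1)
  expect_equal(variance_fold(ra, rb), ra^2 / rb^2, tolerance = 1e-12)
  expect_error(variance_fold(0.5, 0), "nonzero")
})

test_that("the exponential scan-time model is recovered from its own data", {
  t <- c(3.5, 7, 14, 28)
  r <- 0.8 - exp(-t / 5)
  fit <- fit_exponential(t, r)
  expect_true(fit$converged)
  expect_equal(fit$r_spatmax, 0.8, tolerance = 1e-6)
  expect_equal(fit$a, 5, tolerance = 1e-6)
  # the fitted curve saturates at r_spatmax
  expect_equal(fit$r_spatmax - exp(-1e6 / fit$a), fit$r_spatmax)

  # two points interpolate exactly
  fit2 <- fit_exponential(c(5, 10), 0.7 - exp(-c(5, 10) / 4))
  expect_equal(max(abs(fit2$residuals)), 0, tolerance = 1e-8)

  td <- tidy(fit)
  expect_equal(td$term, c("r_spatmax", "a"))
  expect_equal(td$estimate, c(fit$r_spatmax, fit$a))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 4)

  expect_error(fit_exponential(c(3, 3), c(0.5, 0.6)), "distinct")
})

test_that("the full split-map-correlate pipeline behaves on generator data", {
  cfg <- sim_config(n_volumes = 500, jitter_sd = 0, rng_seed = 11)
  sub <- generate_subject(cfg, 1)
  dl <- sim_dlpfc_mask(cfg$grid)
  curve <- repeatability_curve(sub$series, seeds = cfg$seeds, mask = dl,
                               lengths = c(125, 250))
  expect_equal(curve$points$n_segments, c(4, 2))
  expect_equal(curve$points$scan_time_min, c(125, 250) * 1.7 / 60)
  expect_true(all(abs(curve$pairs$r) <= 1))
  expect_equal(nrow(curve$pairs), 6 + 1)
  # repeatability present: planted signal makes segment maps agree
  expect_gt(curve$points$r_spat_mean[2], 0)

  # two independent noise-only runs correlate near zero (null calibration)
  cfg0 <- sim_config(n_volumes = 250, snr = 0, rng_seed = 12)
  nulls <- vapply(1:8, function(s) {
    sub0 <- generate_subject(cfg0, s)
    maps <- lapply(split_segments(sub0$series, 125), cnm_target_map,
                   seeds = cfg0$seeds)
    spatial_correlation(maps[[1]], maps[[2]], dl)
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(length(nulls)) + 0.02)
})
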