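mk_map <- function(vals, grid) {
  structure(list(values = vals, grid = grid), class = c("target_map", "voxel_map"))
}

test_that("top-K selection takes the strongest voxels with a documented tie rule", {
  g <- tiny_grid(c(8, 8, 8))
  nv <- prod(g$shape)
  dl <- brain_mask(g, rep(TRUE, nv))
  mm_x <- voxel_mm_oracle(g, seq_len(nv))[, 1]

  set.seed(1)
  vals <- runif(nv)
  left_idx <- which(mm_x < 0)
  top <- order(-vals[left_idx])[1:5]
  want <- sort(left_idx[top])
  ts <- select_top_k(mk_map(vals, g), dl, "left", k = 5)
  expect_equal(sort(attr(ts, "linear_index")), want)
  expect_equal(nrow(ts), 5)
  expect_equal(attr(ts, "mean_connectivity"), mean(vals[want]))

  # ties across the k-th rank broken by ascending linear index
  vals2 <- rep(0, nv); vals2[left_idx] <- rep(c(1, 0.5), length.out = length(left_idx))
  ts2 <- select_top_k(mk_map(vals2, g), dl, "left", k = 10)
  ones <- left_idx[vals2[left_idx] == 1]
  expect_equal(attr(ts2, "linear_index"), ones[1:10])

  # full-sort oracle under random ties
  vals3 <- sample(seq(0, 1, by = 0.25), nv, replace = TRUE)
  ts3 <- select_top_k(mk_map(vals3, g), dl, "left", k = 20)
  ord <- left_idx[order(-vals3[left_idx], left_idx)]
  expect_equal(attr(ts3, "linear_index"), ord[1:20])

  # monotone: growing k keeps earlier selections
  ts_small <- select_top_k(mk_map(vals, g), dl, "left", k = 10)
  ts_big <- select_top_k(mk_map(vals, g), dl, "left", k = 30)
  expect_true(all(attr(ts_small, "linear_index") %in% attr(ts_big, "linear_index")))

  # fewer defined voxels than k -> all returned with a warning
  sparse <- rep(NA_real_, nv); sparse[left_idx[1:7]] <- 1:7
  expect_warning(ts4 <- select_top_k(mk_map(sparse, g), dl, "left", k = 100),
                 "only 7")
  expect_equal(nrow(ts4), 7)
})

test_that("target connectivity strength pools hemisphere means", {
  g <- tiny_grid(c(8, 4, 4))
  nv <- prod(g$shape)
  dl <- brain_mask(g, rep(TRUE, nv))
  mm_x <- voxel_mm_oracle(g, seq_len(nv))[, 1]
  vals <- numeric(nv); vals[mm_x < 0] <- 0.2; vals[mm_x > 0] <- 0.4
  m <- mk_map(vals, g)
  L <- select_top_k(m, dl, "left", 10)
  R <- select_top_k(m, dl, "right", 10)
  st <- target_connectivity_strength(m, L, R)
  expect_equal(st$strength[st$hemisphere == "left"], 0.2)
  expect_equal(st$strength[st$hemisphere == "right"], 0.4)
  expect_equal(st$strength[st$hemisphere == "pooled"], 0.3)

  set.seed(2)
  vals_r <- runif(nv); mr <- mk_map(vals_r, g)
  Lr <- select_top_k(mr, dl, "left", 12)
  str <- target_connectivity_strength(mr, Lr, Lr, pool = FALSE)
  expect_equal(str$strength[1], mean(vals_r[attr(Lr, "linear_index")]))
})

test_that("overlap maps count subjects per voxel as percentages", {
  g <- tiny_grid(c(8, 8, 8))
  nv <- prod(g$shape)
  dl <- brain_mask(g, rep(TRUE, nv))

  set.seed(3)
  one <- select_top_k(mk_map(runif(nv), g), dl, "left", 50)
  om1 <- group_overlap_map(list(one), g)
  expect_true(all(om1$values %in% c(0, 100)))

  # two disjoint sets -> 50 at every selected voxel
  mm_x <- voxel_mm_oracle(g, seq_len(nv))[, 1]
  lh <- which(mm_x < 0)
  v1 <- rep(0, nv); v1[lh[1:10]] <- 1
  v2 <- rep(0, nv); v2[lh[21:30]] <- 1
  s1 <- select_top_k(mk_map(v1, g), dl, "left", 10)
  s2 <- select_top_k(mk_map(v2, g), dl, "left", 10)
  om2 <- group_overlap_map(list(s1, s2), g)
  sel <- c(attr(s1, "linear_index"), attr(s2, "linear_index"))
  expect_true(all(om2$values[sel] == 50))
  expect_true(all(om2$values[-sel] == 0))

  # counting oracle, n = 7 random subjects
  sets <- lapply(1:7, function(i) select_top_k(mk_map(runif(nv), g), dl, "left", 30))
  om7 <- group_overlap_map(sets, g)
  counts <- numeric(nv)
  for (s in sets) for (l in attr(s, "linear_index")) counts[l] <- counts[l] + 1
  expect_equal(om7$values, 100 * counts / 7)
  expect_equal(om7$n_subjects, 7)
  # subject-order invariance and the mass identity
  om7b <- group_overlap_map(rev(sets), g)
  expect_equal(om7b$values, om7$values)
  expect_equal(sum(om7$values / 100), 7 * 30 / 7)
  expect_true(all(om7$values >= 0 & om7$values <= 100))
  expect_equal(om7$argmax_pct, max(om7$values))
})

test_that("peak distances recompute from argmax MNI coordinates", {
  g <- tiny_grid(c(8, 8, 8))
  nv <- prod(g$shape)
  mask <- brain_mask(g, rep(TRUE, nv))

  set.seed(4)
  v <- runif(nv)
  same <- list(mk_map(v, g), mk_map(v, g), mk_map(v, g))
  pd0 <- peak_distances(same, mask)
  expect_equal(pd0$distances$distance_mm, rep(0, 3))
  expect_equal(pd0$mean, 0)

  i1 <- voxel_mm_oracle(g, seq_len(nv))
  v1 <- rep(0, nv); v2 <- rep(0, nv)
  a <- which(i1[, 1] == 0 & i1[, 2] == 0 & i1[, 3] == 0)
  b <- which(i1[, 1] == 3 & i1[, 2] == 0 & i1[, 3] == 0)
  v1[a] <- 1; v2[b] <- 1
  expect_equal(peak_distances(list(mk_map(v1, g), mk_map(v2, g)), mask)$mean, 3)

  maps <- lapply(1:5, function(i) mk_map(runif(nv), g))
  pd <- peak_distances(maps, mask)
  peaks <- t(sapply(maps, function(m) {
    idx <- which(as.vector(mask$voxels))
    best <- idx[which.max(m$values[idx])]
    voxel_mm_oracle(g, best)[1, ]
  }))
  k <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    k <- k + 1
    expect_equal(pd$distances$distance_mm[k],
                 sqrt(sum((peaks[i, ] - peaks[j, ])^2)), tolerance = 1e-12)
  }
  expect_equal(pd$mean, mean(pd$distances$distance_mm))
  expect_equal(pd$sd, sd(pd$distances$distance_mm))
})

test_that("coordinate extraction reads the nearest voxel of the group mean", {
  g <- tiny_grid(c(6, 6, 6))
  nv <- prod(g$shape)
  set.seed(5)
  m1 <- mk_map(runif(nv), g); m2 <- mk_map(runif(nv), g)

  centre <- voxel_mm_oracle(g, 50)[1, ]
  got <- extract_at_coordinates(list(m1), data.frame(x = centre[1], y = centre[2],
                                                     z = centre[3]))
  expect_equal(got$value, m1$values[50])

  both <- extract_at_coordinates(list(m1, m2),
                                 data.frame(x = centre[1], y = centre[2],
                                            z = centre[3]))
  expect_equal(both$value, (m1$values[50] + m2$values[50]) / 2)

  # off-centre coordinate resolves to the nearest voxel (brute-force scan)
  off <- centre + c(1.2, -0.9, 1.4)
  mm <- voxel_mm_oracle(g, seq_len(nv))
  nearest <- which.min(rowSums(sweep(mm, 2, off)^2))
  gote <- extract_at_coordinates(list(m1), t(off))
  expect_equal(gote$value, m1$values[nearest])

  expect_error(extract_at_coordinates(list(m1), data.frame(x = 999, y = 0, z = 0)),
               "999")
})

test_that("outcome correlation residualizes on covariates before correlating", {
  set.seed(6)
  n <- 30
  cov <- data.frame(device = sample(c("A", "B"), n, TRUE),
                    protocol = sample(c("p10", "p20"), n, TRUE),
                    n_sessions = sample(20:32, n, TRUE))
  X <- model.matrix(~ ., cov)
  strengths <- 0.2 * X[, 2] + rnorm(n, 0, 0.1)
  outcome <- 5 * strengths + 3 * X[, 3] + rnorm(n)

  res <- adjusted_outcome_correlation(strengths, outcome, cov)
  plain <- cor.test(strengths, outcome)
  expect_equal(res$r[res$method == "pearson"], unname(plain$estimate))
  expect_equal(res$p_value[res$method == "pearson"], plain$p.value)

  # two-stage OLS oracle
  rx <- ols_residual_oracle(X, strengths)
  ry <- ols_residual_oracle(X, outcome)
  r_part <- pearson_oracle(as.vector(rx), as.vector(ry))
  row <- res[res$method == "partial", ]
  expect_equal(row$r, r_part, tolerance = 1e-12)
  q <- ncol(X) - 1
  expect_equal(row$df, n - 2 - q)
  tstat <- r_part * sqrt((n - 2 - q) / (1 - r_part^2))
  expect_equal(row$p_value, 2 * pt(-abs(tstat), n - 2 - q), tolerance = 1e-12)

  # adjust off equals plain Pearson only
  res0 <- adjusted_outcome_correlation(strengths, outcome)
  expect_equal(nrow(res0), 1)

  # covariate identical to strengths -> undefined partial correlation
  expect_error(adjusted_outcome_correlation(strengths, outcome,
                                            data.frame(s = strengths)),
               "undefined")
  expect_error(adjusted_outcome_correlation(rep(1, n), outcome), "constant")
})
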