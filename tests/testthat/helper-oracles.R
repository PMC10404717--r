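# Shared fixtures and independent brute-force oracles.
# Oracles are written from first principles (loops, textbook formulas) and
# never call the code paths they check.

tiny_grid <- function(shape = c(6, 6, 6), voxel_size = 3,
                      origin = -voxel_size * (shape %/% 2)) {
  volume_grid(shape, mni_affine(voxel_size, origin))
}

random_series <- function(grid, nt, seed = 1, tr = 2) {
  set.seed(seed)
  bold_series(matrix(rnorm(nt * prod(grid$shape)), nrow = nt), grid, tr = tr)
}

random_mask <- function(grid, p = 0.3, seed = 1) {
  set.seed(seed)
  brain_mask(grid, runif(prod(grid$shape)) < p)
}

# textbook Pearson correlation via explicit sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# per-volume mean over mask voxels by explicit double loop
mask_mean_oracle <- function(data, mask_lin) {
  vapply(seq_len(nrow(data)), function(t) {
    acc <- 0
    for (v in mask_lin) acc <- acc + data[t, v]
    acc / length(mask_lin)
  }, numeric(1))
}

# FD (Power) by direct per-volume evaluation
fd_oracle <- function(m, head_radius = 50) {
  out <- numeric(nrow(m))
  for (i in 2:nrow(m)) {
    out[i] <- sum(abs(m[i, 1:3] - m[i - 1, 1:3])) +
      head_radius * sum(abs(m[i, 4:6] - m[i - 1, 4:6]))
  }
  out
}

# OLS residuals via the normal equations
ols_residual_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  y - X %*% beta
}

# mm coordinates of every voxel, recomputed independently of grid_voxel_mm
voxel_mm_oracle <- function(grid, lin) {
  out <- matrix(NA_real_, length(lin), 3)
  for (r in seq_along(lin)) {
    l <- lin[r] - 1
    k <- l %/% (grid$shape[1] * grid$shape[2])
    j <- (l %% (grid$shape[1] * grid$shape[2])) %/% grid$shape[1]
    i <- l %% grid$shape[1]
    out[r, ] <- (grid$affine %*% c(i, j, k, 1))[1:3]
  }
  out
}
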