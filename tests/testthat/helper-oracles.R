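# Independent brute-force reference for quantile normalization: sort each
# column, average order statistics, substitute back by order().  Kept
# deliberately loop-based and separate from the package implementation.
brute_force_quantile <- function(x) {
  m <- nrow(x)
  sorted <- matrix(0, m, ncol(x))
  for (j in seq_len(ncol(x))) sorted[, j] <- sort(x[, j])
  q <- numeric(m)
  for (r in seq_len(m)) q[r] <- mean(sorted[r, ])
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    for (r in seq_len(m)) out[o[r], j] <- q[r]
  }
  out
}

# Small tie-free random dataset wrapped in the package container.
random_dataset <- function(m, n, sd = 1) {
  expr_dataset(matrix(rnorm(m * 2 * n, sd = sd), m, 2 * n),
               group = rep(c("A", "B"), each = n),
               truth = rep("NDEG", m))
}

# Kolmogorov-Smirnov distance between a sample and a gridded density:
# integrates the density to a CDF by the trapezoid rule and takes the sup
# gap against the empirical CDF on the grid.
ks_distance_to_density <- function(sample, grid, dens) {
  dx <- diff(grid)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dx))
  cdf <- cdf / max(cdf)
  emp <- ecdf(sample)(grid)
  max(abs(emp - cdf))
}
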