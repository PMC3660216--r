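test_that("the central t density has its closed forms and symmetry", {
  expect_equal(t_density_central(0, nu = 1), 1 / pi)
  x <- seq(-8, 8, by = 0.01)
  expect_equal(t_density_central(x, 5), t_density_central(-x, 5))
  expect_equal(sum(t_density_central(seq(-60, 60, by = 0.01), 3)) * 0.01,
               1, tolerance = 1e-4)
  expect_error(t_density_central(0, nu = 0), "nu")
})

test_that("the noncentral t density reduces and shifts correctly", {
  x <- seq(-6, 6, by = 0.1)
  expect_equal(t_density_noncentral(x, 7, gamma = 0),
               t_density_central(x, 7), tolerance = 1e-10)
  # positive noncentrality moves the mode to positive x
  g <- seq(-10, 10, by = 0.01)
  f <- t_density_noncentral(g, 7, gamma = 3)
  expect_gt(g[which.max(f)], 0)
})

test_that("the doubly noncentral t density reduces through the chain", {
  x <- seq(-6, 6, by = 0.25)
  expect_equal(t_density_doubly_noncentral(x, 9, gamma = 2, lambda = 0),
               t_density_noncentral(x, 9, 2), tolerance = 1e-8)
  expect_equal(
    t_density_doubly_noncentral(x, 9, gamma = 0, lambda = 0),
    t_density_central(x, 9), tolerance = 1e-8)
  expect_error(t_density_doubly_noncentral(x, 9, 1, lambda = -1),
               "lambda")
})

test_that("the doubly noncentral t density matches its sampling law", {
  # moderate-size Monte-Carlo check; the acceptance suite runs the
  # full-size one
  x <- seq(-4, 12, by = 0.02)
  fx <- t_density_doubly_noncentral(x, 18, gamma = 5, lambda = 40)
  expect_equal(sum(fx) * 0.02, 1, tolerance = 1e-3)
  set.seed(71)
  mc <- (rnorm(1e5) + 5) / sqrt(rchisq(1e5, 18, ncp = 40) / 18)
  expect_lt(ks_distance_to_density(mc, x, fx), 0.01)
})

test_that("mixture weights follow the rank-occupancy probabilities", {
  w <- mixture_weights(1000, 60, 40, 10, "UP")
  expect_equal(w$w_central, 0.06^10)
  expect_equal(w$w_noncentral, 0.9^10 + 0.04^10)
  expect_equal(w$w_central + w$w_noncentral + w$w_doubly, 1)
  expect_lt(w$w_central, 1e-12)  # negligible for realistic designs
  # n = 1: weights are the raw block proportions
  w1 <- mixture_weights(1000, 60, 40, 1, "UP")
  expect_equal(unlist(w1), c(w_central = 0.06, w_noncentral = 0.94,
                             w_doubly = 0))
  # balanced designs are direction-symmetric
  expect_equal(mixture_weights(100, 10, 10, 4, "UP"),
               mixture_weights(100, 10, 10, 4, "DOWN"))
  # swapping the block sizes mirrors UP and DOWN
  expect_equal(mixture_weights(100, 15, 5, 4, "UP"),
               mixture_weights(100, 5, 15, 4, "DOWN"))
  expect_error(mixture_weights(10, 8, 8, 2), "inconsistent")
})

test_that("mixture density is a proper convex combination", {
  p_central <- mixture_t_params(9, gamma = 4, lambda = 10,
                                weights = c(1, 0, 0))
  x <- seq(-6, 6, by = 0.1)
  expect_equal(mixture_density(x, p_central), t_density_central(x, 9))
  p <- mixture_t_params(9, gamma = 4, lambda = 10,
                        weights = c(0.2, 0.5, 0.3))
  g <- seq(-30, 30, by = 0.02)
  f <- mixture_density(g, p)
  expect_true(all(f >= 0))
  expect_equal(sum(f) * 0.02, 1, tolerance = 1e-4)
  expect_error(mixture_t_params(9, 1, 1, weights = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("calibrated mixture theory matches simulated mode locations", {
  d <- simu_design(m = 1000, m1_up = 60, m1_down = 40, n = 10,
                   sigma = 0.35, rho = 0.9, e_up = 4, e_down = -4,
                   seed = 72)
  n_rep <- 60
  params <- calibrate_mixture_params(d, n_replicates = n_rep)
  expect_s3_class(params, "mixture_t_params")
  expect_equal(params$nu, 18)
  expect_gt(params$gamma, 0)
  expect_gt(params$lambda, 0)
  # pooled up-gene t statistics across the same replicates
  ts <- c()
  for (r in seq_len(n_rep)) {
    dr <- d
    dr$seed <- d$seed + r
    tab <- t_test_genes(quantile_normalize(simulate_simu(dr)))
    ts <- c(ts, tab$statistic[tab$truth == "UP"])
  }
  kde <- density(ts, bw = "nrd0", n = 1024)
  sim_modes <- density_modes(tibble::tibble(x = kde$x, density = kde$y),
                             min_height = 0.02)$x
  grid <- seq(min(kde$x), max(kde$x), by = 0.02)
  theo <- suppressWarnings(mixture_density(grid, params))
  theo_modes <- density_modes(tibble::tibble(x = grid, density = theo),
                              min_height = 0.001)$x
  expect_gte(length(sim_modes), 2)   # interior + outer
  expect_gte(length(theo_modes), 2)
  # mode locations agree to within the KDE's own resolution (one
  # bandwidth): the kernel smoother cannot localize a peak more finely
  for (sm in sim_modes) {
    expect_lt(min(abs(theo_modes - sm)), kde$bw)
  }
})

test_that("rank-normalized group differences have the predicted limit", {
  expect_equal(rank_expected_difference(1000, 60, 40, "UP"), 0.47)
  expect_equal(rank_expected_difference(1000, 60, 40, "DOWN"), -0.48)
  expect_equal(rank_expected_difference(100, 100, 0, "UP"), 0)
})

test_that("rank asymptotic supports partition the unit interval", {
  up_a <- rank_asymptotic_support("UP", "A", 1000, 60, 40)
  expect_equal(c(up_a$lower, up_a$upper), c(0.94, 1))
  down_a <- rank_asymptotic_support("DOWN", "A", 1000, 60, 40)
  expect_equal(c(down_a$lower, down_a$upper), c(0, 0.04))
  ndeg_a <- rank_asymptotic_support("NDEG", "A", 1000, 60, 40)
  expect_equal(c(ndeg_a$lower, ndeg_a$upper), c(0.04, 0.94))
  for (cls in c("UP", "DOWN", "NDEG")) {
    b <- rank_asymptotic_support(cls, "B", 1000, 60, 40)
    expect_equal(c(b$lower, b$upper), c(0, 1))
  }
  # widths match the block proportions
  expect_equal(up_a$upper - up_a$lower, 60 / 1000)
  expect_equal(down_a$upper - down_a$lower, 40 / 1000)
})

test_that("mixture parameter objects tidy into one row", {
  p <- mixture_t_params(18, 5, 40, c(0.1, 0.4, 0.5), "DOWN")
  td <- tidy(p)
  expect_equal(nrow(td), 1)
  expect_equal(td$lambda, 40)
  expect_equal(td$direction, "DOWN")
})
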