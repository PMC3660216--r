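test_that("design constructor validates its parameters", {
  d <- simu_design(m = 10, m1_up = 2, m1_down = 1, n = 3, seed = 1)
  expect_s3_class(d, "simu_design")
  expect_error(simu_design(m = 5, m1_up = 4, m1_down = 2), "exceed")
  expect_error(simu_design(rho = 1), "rho")
  expect_error(simu_design(rho = -0.1), "rho")
  expect_error(simu_design(sigma = 0), "sigma")
  expect_error(simu_design(e_up = -1), "e_up")
  expect_error(simu_design(e_down = 1), "e_down")
  expect_error(simu_design(n = 1), "n")
})

test_that("equicorrelated noise reproduces the stated marginal moments", {
  set.seed(101)
  x <- equicorrelated_noise(2, 10000, sigma = 0.35, rho = 0.9)
  expect_equal(sd(x[1, ]), 0.35, tolerance = 0.01 / 0.35)
  expect_equal(sd(x[2, ]), 0.35, tolerance = 0.01 / 0.35)
  expect_equal(cor(x[1, ], x[2, ]), 0.9, tolerance = 0.02 / 0.9)
})

test_that("rho = 0 yields uncorrelated rows with identity covariance", {
  set.seed(102)
  x <- equicorrelated_noise(5, 10000, sigma = 1, rho = 0)
  cv <- cov(t(x))
  expect_equal(diag(cv), rep(1, 5), tolerance = 0.05,
               ignore_attr = TRUE)
  off <- cv[upper.tri(cv)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("average pairwise correlation over random gene pairs recovers rho", {
  set.seed(103)
  x <- equicorrelated_noise(50, 10000, sigma = 0.35, rho = 0.9)
  pairs <- replicate(100, sample.int(50, 2))
  r <- apply(pairs, 2, function(ij) cor(x[ij[1], ], x[ij[2], ]))
  expect_lt(abs(mean(r) - 0.9), 0.02)
})

test_that("noise generation rejects invalid parameters and is deterministic", {
  expect_error(equicorrelated_noise(2, 3, 1, 1), "rho")
  expect_error(equicorrelated_noise(2, 3, 1, -0.2), "rho")
  expect_error(equicorrelated_noise(0, 3, 1, 0.5), "positive")
  expect_error(equicorrelated_noise(2, 3, -1, 0.5), "sigma")
  set.seed(7); a <- equicorrelated_noise(4, 6, 0.35, 0.9)
  set.seed(7); b <- equicorrelated_noise(4, 6, 0.35, 0.9)
  expect_identical(a, b)
})

test_that("simulated datasets carry the expected mean structure", {
  # large n so empirical group differences pin down the design means
  d <- simu_design(m = 3, m1_up = 1, m1_down = 1, n = 10000, sigma = 1,
                   rho = 0, e_up = 5, e_down = -5, seed = 11)
  ds <- simulate_simu(d)
  a <- ds$values[, ds$group == "A"]
  b <- ds$values[, ds$group == "B"]
  diff <- rowMeans(a) - rowMeans(b)
  se <- sqrt(2 / 10000)   # sd 1 per entry, two groups
  expect_equal(ds$truth, c("UP", "DOWN", "NDEG"))
  expect_lt(abs(diff[1] - 5), 3 * se)
  expect_lt(abs(diff[2] + 5), 3 * se)
  expect_lt(abs(diff[3]), 3 * se)
})

test_that("the standard equicorrelated design recovers its effect size", {
  d <- simu_design(m = 1000, m1_up = 60, m1_down = 40, n = 10,
                   sigma = 0.35, rho = 0.9, e_up = 2, e_down = -2,
                   seed = 12)
  ds <- simulate_simu(d)
  a <- ds$values[, ds$group == "A"]
  b <- ds$values[, ds$group == "B"]
  up_diff <- mean(rowMeans(a[ds$truth == "UP", ]) -
                    rowMeans(b[ds$truth == "UP", ]))
  # genes are equicorrelated at 0.9, so averaging over the 60 UP genes
  # barely shrinks the standard error of a single gene's difference
  se_single <- 0.35 * sqrt(2 / 10)
  expect_lt(abs(up_diff - 2), 3 * se_single)
  expect_equal(sum(ds$truth == "UP"), 60)
  expect_equal(sum(ds$truth == "DOWN"), 40)
  expect_equal(sum(ds$group == "A"), 10)
})

test_that("identical seeds give bit-identical datasets", {
  d <- simu_design(m = 50, m1_up = 5, m1_down = 5, n = 4, e_up = 1,
                   e_down = -1, seed = 99)
  expect_identical(simulate_simu(d), simulate_simu(d))
})

test_that("pooled SD over null genes recovers sigma", {
  set.seed(104)
  x <- equicorrelated_noise(200, 200, sigma = 0.35, rho = 0)
  pooled <- sqrt(mean(apply(x, 1, var)))
  expect_equal(pooled, 0.35, tolerance = 0.01)
})

test_that("per-gene t-test p-values are uniform under the global null", {
  # independent genes so the Kolmogorov-Smirnov band applies
  d <- simu_design(m = 1000, m1_up = 0, m1_down = 0, n = 10,
                   sigma = 0.35, rho = 0, seed = 13)
  tab <- t_test_genes(identity_normalize(simulate_simu(d)))
  ks <- suppressWarnings(ks.test(tab$p_raw, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("heterogeneous effect profiles shift means and label truth", {
  expect_error(
    simulate_bio_like(simu_design(m = 10, m1_up = 0, m1_down = 0, n = 2,
                                  seed = 1), rep(0, 5)),
    "length")
  d <- simu_design(m = 3, m1_up = 0, m1_down = 0, n = 10000, sigma = 1,
                   rho = 0, seed = 14)
  ds <- simulate_bio_like(d, gene_effects = c(1, -1, 0),
                          extra_effect = 0.5)
  diff <- rowMeans(ds$values[, ds$group == "A"]) -
    rowMeans(ds$values[, ds$group == "B"])
  se <- sqrt(2 / 10000)
  expect_equal(ds$truth, c("UP", "DOWN", "NDEG"))
  expect_lt(abs(diff[1] - 1.5), 3 * se)
  expect_lt(abs(diff[2] + 1.5), 3 * se)
  expect_lt(abs(diff[3]), 3 * se)
})

test_that("an unbalanced profile reports its UP/DOWN composition", {
  set.seed(15)
  eff <- random_gene_effects(1000, m1_up = 677, m1_down = 57)
  d <- simu_design(m = 1000, n = 5, seed = 16)
  ds <- simulate_bio_like(d, eff)
  expect_equal(sum(ds$truth == "UP"), 677)
  expect_equal(sum(ds$truth == "DOWN"), 57)
  expect_equal(sum(ds$truth == "NDEG"), 1000 - 677 - 57)
})

test_that("zero effect profiles reduce to the global null law", {
  d <- simu_design(m = 20, m1_up = 0, m1_down = 0, n = 3, seed = 17)
  a <- simulate_bio_like(d, rep(0, 20), extra_effect = 0)
  b <- simulate_simu(d)
  expect_identical(a$values, b$values)
})

test_that("datasets tidy into long tibbles and glance into one row", {
  d <- simu_design(m = 6, m1_up = 2, m1_down = 1, n = 2, seed = 18)
  ds <- simulate_simu(d)
  td <- tidy(ds)
  expect_equal(nrow(td), 6 * 4)
  expect_named(td, c("gene_id", "array_id", "group", "truth", "method",
                     "value"))
  g <- glance(ds)
  expect_equal(g$m1_up, 2)
  expect_equal(g$n_per_group, 2)
})
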