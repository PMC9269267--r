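test_that("noiseless simulations lie exactly on the cumulative curve", {
  p <- example_params(delta = 1.5)
  d <- simulation_design(p, times = seq(0, 40, by = 5), replicates_per_time = 2,
                         noise_scale = 0, seed = 3)
  s <- simulate_growth_series(d)
  expect_equal(s$sizes, growth_cumulative(s$times, p), tolerance = 1e-12)
  expect_length(s$times, 9 * 2)
})

test_that("simulations are reproducible from the seed", {
  d1 <- design_crops_like(seed = 11)
  expect_identical(simulate_growth_series(d1), simulate_growth_series(d1))
  d2 <- design_crops_like(seed = 12)
  expect_false(identical(simulate_growth_series(d1), simulate_growth_series(d2)))
})

test_that("replicate means converge to the curve value (law of large numbers)", {
  p <- example_params(delta = 1.2)
  sigma <- 0.8
  d <- simulation_design(p, times = 20, replicates_per_time = 1000,
                         noise_scale = sigma, seed = 21)
  s <- simulate_growth_series(d)
  mu <- growth_cumulative(20, p)
  se <- sigma / sqrt(1000)
  expect_lt(abs(mean(s$sizes) - mu), 3 * se)
})

test_that("negative draws are clamped and series invariants always hold", {
  p <- example_params()
  d <- simulation_design(p, times = c(0, 1, 2, 30), replicates_per_time = 50,
                         noise_scale = 50, seed = 2)  # sizes near 0, huge noise
  s <- simulate_growth_series(d)
  expect_true(all(s$sizes >= 0))
  expect_s3_class(s, "growth_series")
  dl <- simulation_design(p, times = c(10, 20), replicates_per_time = 5,
                          noise_model = "multiplicative_lognormal",
                          noise_scale = 0.1, seed = 4)
  sl <- simulate_growth_series(dl)
  expect_true(all(sl$sizes > 0))
})

test_that("additive-Gaussian residuals are unskewed at large n", {
  p <- example_params(delta = 1.3)
  d <- simulation_design(p, times = 25, replicates_per_time = 1e4,
                         noise_scale = 1, seed = 31)
  s <- simulate_growth_series(d)
  z <- s$sizes - growth_cumulative(25, p)
  skew <- mean(z^3) / stats::sd(z)^3
  expect_lt(abs(skew), 0.2)
})

test_that("designs validate their inputs", {
  p <- example_params()
  expect_error(simulation_design(p, times = c(-1, 2)), "non-negative")
  expect_error(simulation_design(p, times = 1:3, replicates_per_time = 0),
               ">= 1")
  expect_error(simulation_design(p, times = 1:3, noise_scale = -1),
               "non-negative")
  expect_error(simulate_growth_series(list()), "simulation_design")
})

test_that("simulated leaf outlines are closed and seed-reproducible", {
  up <- growth_params(0.02, 3, 0, 10, delta = 1.5)
  o <- simulate_leaf_outline(up, up, n_points = 60, noise_scale = 0.01, seed = 5)
  expect_true(o$closed)
  expect_equal(o$points[1, ], o$points[nrow(o$points), ])
  o2 <- simulate_leaf_outline(up, up, n_points = 60, noise_scale = 0.01, seed = 5)
  expect_identical(o$points, o2$points)
})

test_that("equal half parameters give an axially symmetric outline", {
  up <- growth_params(0.05, 2, 0, 8, delta = 1.2)
  o <- simulate_leaf_outline(up, up, n_points = 80, noise_scale = 0)
  pts <- o$points[-nrow(o$points), ]
  for (i in seq_len(nrow(pts))) {
    mirrored <- which(abs(pts[, 1] - pts[i, 1]) < 1e-12 &
                        abs(pts[, 2] + pts[i, 2]) < 1e-12)
    expect_gte(length(mirrored), 1)
  }
})

test_that("leaf simulation rejects mismatched halves and tiny outlines", {
  up <- growth_params(0.02, 3, 0, 10)
  lo <- growth_params(0.02, 3, 0, 12)
  expect_error(simulate_leaf_outline(up, lo), "share x_min")
  expect_error(simulate_leaf_outline(up, up, n_points = 10), "at least 20")
})
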