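test_that("compute_rmse is sqrt(rss/n) and rejects bad input", {
  expect_identical(compute_rmse(0, 10), 0)
  expect_identical(compute_rmse(4, 4), 1)
  set.seed(5)
  for (i in 1:10) {
    r <- rnorm(20)
    expect_equal(compute_rmse(sum(r^2), length(r)), sqrt(mean(r^2)),
                 tolerance = 1e-14)
  }
  expect_error(compute_rmse(-1, 5), "non-negative")
  expect_error(compute_rmse(4, 0), "at least 1")
})

test_that("growth_series validates its invariants", {
  expect_error(growth_series(1:3, 1:2), "equal length")
  expect_error(growth_series(numeric(0), numeric(0)), "at least one")
  expect_error(growth_series(c(1, Inf), c(1, 2)), "finite")
  expect_error(growth_series(1:2, c(1, -2)), "non-negative")
  s <- growth_series(c(1, 1, 2), c(0, 0.5, 1), label = "ok")
  expect_s3_class(s, "growth_series")
})

test_that("a noiseless MBE trajectory returns its generating parameters", {
  truth <- growth_params(5e-5, 2.5, 0, 40, delta = 1.8)
  s <- noiseless_series(truth)
  f <- fit_growth(s, "MBE", fix_x_min = 0, seed = 1)
  est <- coef(f)[c("a", "m", "x_max", "delta")]
  tru <- unlist(unclass(truth))[c("a", "m", "x_max", "delta")]
  expect_lt(max(abs(est - tru) / tru), 1e-3)
  expect_identical(coef(f)[["x_min"]], 0)
  expect_equal(f$rmse, sqrt(f$rss / f$n))
})

test_that("fitting the MBE to BE-generated data drives delta to one", {
  truth <- growth_params(0.008, 3, 0, 35, delta = 1)
  s <- noiseless_series(truth)
  f <- fit_growth(s, "MBE", fix_x_min = 0, seed = 1)
  expect_lt(abs(coef(f)[["delta"]] - 1), 1e-2)
})

test_that("a BE fit always reports delta = 1 and respects preconditions", {
  s <- noiseless_series(example_params())
  f <- fit_growth(s, "BE", fix_x_min = 0, seed = 1)
  expect_identical(coef(f)[["delta"]], 1)
  tiny <- growth_series(c(1, 2, 3), c(0.1, 0.5, 1))
  expect_error(fit_growth(tiny, "MBE", fix_x_min = 0), "too few observations")
  expect_error(fit_growth(growth_series(c(0, 1, 2, 3, 4), 0:4 / 4), "BE",
                          fix_x_min = 2),
               ">= the fixed x_min")
})

test_that("fits are bit-reproducible given the same seed and restarts", {
  s <- simulate_growth_series(
    simulation_design(example_params(delta = 1.5), times = seq(2, 33, by = 3),
                      noise_scale = 0.3, seed = 9))
  f1 <- fit_growth(s, "BE", fix_x_min = 0, seed = 5, n_restarts = 12)
  f2 <- fit_growth(s, "BE", fix_x_min = 0, seed = 5, n_restarts = 12)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
  f3 <- fit_growth(s, "BE", fix_x_min = 0, seed = 6, n_restarts = 12)
  expect_equal(f3$rss, f1$rss, tolerance = 1e-4)  # same optimum, other jitter
})

test_that("the MBE fit is never worse than the nested BE fit", {
  set.seed(17)
  for (i in 1:3) {
    s <- simulate_growth_series(design_crops_like(seed = 200 + i))
    res <- compare_growth(s, fix_x_min = 0, seed = i)
    expect_lte(res$fit_mbe$rss, res$fit_be$rss)
  }
})

test_that("model comparison applies the strict 5% APE rule with the BE denominator", {
  cmp <- compare_models(fake_fit("BE", 2.0), fake_fit("MBE", 1.8))
  expect_equal(cmp$ape_percent, 10)
  expect_identical(cmp$preferred, "MBE")
  # tie: zero APE, simpler model wins
  tie <- compare_models(fake_fit("BE", 1.5), fake_fit("MBE", 1.5))
  expect_identical(tie$ape_percent, 0)
  expect_identical(tie$preferred, "BE")
  # APE exactly 5% is not enough (strict inequality)
  at5 <- compare_models(fake_fit("BE", 20), fake_fit("MBE", 19))
  expect_identical(at5$ape_percent, 5)
  expect_identical(at5$preferred, "BE")
  # a *worse* MBE with APE > 5% must not be preferred
  worse <- compare_models(fake_fit("BE", 2.0), fake_fit("MBE", 2.4))
  expect_equal(worse$ape_percent, 20)
  expect_identical(worse$preferred, "BE")
  # the denominator is always the BE's RMSE, whichever fit is better
  expect_equal(worse$ape_percent, abs(2.0 - 2.4) / 2.0 * 100)
  expect_error(compare_models(fake_fit("BE", 0), fake_fit("MBE", 1)),
               "undefined")
  expect_error(compare_models(fake_fit("BE", 1, n = 10),
                              fake_fit("MBE", 1, n = 12)),
               "same series")
  expect_error(compare_models(fake_fit("MBE", 1), fake_fit("MBE", 1)),
               "in that order")
})

test_that("fit methods expose residuals, predictions and simulation", {
  truth <- example_params(delta = 1.5)
  s <- noiseless_series(truth, n = 12)
  f <- fit_growth(s, "MBE", fix_x_min = 0, seed = 1)
  expect_equal(sum(residuals(f)^2), f$rss, tolerance = 1e-12)
  expect_equal(fitted(f) + residuals(f), s$sizes)
  # plateau prediction beyond the fitted end of growth
  plateau <- predict(f, newdata = coef(f)[["x_max"]] + c(0, 50))
  expect_equal(plateau[1], plateau[2], tolerance = 1e-12)
  expect_equal(predict(f, newdata = 10, type = "rate"),
               rate_mbe(10, f$params))
  sims <- simulate(f, nsim = 3, seed = 2)
  expect_identical(dim(sims), c(12L, 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 2))
  expect_output(print(summary(f)), "maximum growth rate")
})
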