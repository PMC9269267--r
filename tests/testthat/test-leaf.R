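# half-width profiles clearly narrower than the leaf length, so the
# base-apex segment is the outline's diameter
up_truth <- function() growth_params(0.003, 3, 0, 10, delta = 1.5)
lo_truth <- function() growth_params(0.022, 2.2, 0, 10, delta = 1.1)

test_that("registration is idempotent on an already-registered outline", {
  o <- simulate_leaf_outline(up_truth(), lo_truth(), n_points = 80)
  r1 <- register_leaf(o)
  r2 <- register_leaf(r1)
  expect_lt(max(abs(r1$points - r2$points)), 1e-10)
})

test_that("registration undoes a known rigid motion and records it", {
  o <- simulate_leaf_outline(up_truth(), lo_truth(), n_points = 80)
  ref <- register_leaf(o)$points
  ang <- pi / 2
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  shift <- c(4.5, -2)
  moved <- sweep(o$points %*% t(R), 2, -shift)
  reg <- register_leaf(leaf_outline(moved))
  expect_lt(max(abs(reg$points - ref)), 1e-8)
  rec <- attr(reg, "registration")
  # the recorded rotation undoes the applied one (mod 2 pi)
  expect_lt(abs(((rec$angle + ang + pi) %% (2 * pi)) - pi), 1e-8)
})

test_that("registration is an isometry: pairwise distances are preserved", {
  o <- simulate_leaf_outline(up_truth(), lo_truth(), n_points = 60,
                             noise_scale = 0.02, seed = 8)
  d0 <- stats::dist(o$points)
  d1 <- stats::dist(register_leaf(o)$points)
  expect_lt(max(abs(d1 - d0)) / max(d0), 1e-10)
})

test_that("degenerate outlines are rejected", {
  line <- cbind(x = seq(0, 5, length.out = 25), y = rep(1, 25))
  expect_error(register_leaf(leaf_outline(line)), "collinear")
  expect_error(leaf_outline(cbind(0:25, NA)), "finite")
})

test_that("a noiseless asymmetric outline returns both half parameter sets", {
  o <- simulate_leaf_outline(up_truth(), lo_truth(), n_points = 100)
  fit <- fit_leaf(register_leaf(o))
  for (half in c("upper_params", "lower_params")) {
    tru <- unlist(unclass(if (half == "upper_params") up_truth() else lo_truth()))
    est <- unlist(unclass(fit[[half]]))
    free <- c("a", "m", "delta")
    expect_lt(max(abs(est[free] - tru[free]) / tru[free]), 1e-3)
  }
  expect_identical(fit$upper_params$x_min, 0)
  expect_equal(fit$upper_params$x_max, 10, tolerance = 1e-12)
})

test_that("the symmetric fit nests inside the asymmetric fit", {
  sym <- simulate_leaf_outline(up_truth(), up_truth(), n_points = 80)
  fs <- fit_leaf(register_leaf(sym), symmetric = TRUE)
  expect_lt(fs$rss, 1e-10)
  asym <- simulate_leaf_outline(up_truth(), lo_truth(), n_points = 80)
  r <- register_leaf(asym)
  expect_gte(fit_leaf(r, symmetric = TRUE)$rss, fit_leaf(r)$rss)
})

test_that("leaf fits are invariant to point order and rigid motions", {
  o <- simulate_leaf_outline(up_truth(), lo_truth(), n_points = 80,
                             noise_scale = 0.01, seed = 13)
  f0 <- fit_leaf(register_leaf(o))
  # shuffled point cloud (open trace)
  set.seed(1)
  sh <- leaf_outline(o$points[sample(nrow(o$points) - 1), ], closed = FALSE)
  f1 <- fit_leaf(register_leaf(sh))
  expect_equal(f1$rss, f0$rss, tolerance = 1e-6)
  # rotated + translated copy
  ang <- -0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  mv <- leaf_outline(sweep(o$points %*% t(R), 2, c(-3, 11)))
  f2 <- fit_leaf(register_leaf(mv))
  expect_equal(f2$rss, f0$rss, tolerance = 1e-6)
})

test_that("margins with too few points are refused", {
  up <- up_truth()
  pts <- rbind(cbind(seq(0, 10, length.out = 22),
                     rate_mbe(seq(0, 10, length.out = 22), up)),
               c(5, -0.01), c(6, -0.01), c(7, -0.01))
  o <- leaf_outline(pts, closed = FALSE)
  reg <- register_leaf(o)
  expect_error(fit_leaf(reg), "too few points per margin")
})
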