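# Shared fixtures: all data are generated in code.

# the worked-example parameter set used throughout the docs
example_params <- function(delta = 1) {
  growth_params(a = 0.01, m = 3, x_min = 0, x_max = 35, delta = delta)
}

# draw a random valid parameter set (caller controls the RNG state)
random_params <- function(delta = NULL, x_min = NULL) {
  if (is.null(x_min)) x_min <- stats::runif(1, -5, 10)
  growth_params(a = 10^stats::runif(1, -4, 0),
                m = stats::runif(1, 0.5, 5),
                x_min = x_min,
                x_max = x_min + stats::runif(1, 5, 50),
                delta = if (is.null(delta)) stats::runif(1, 0.3, 3) else delta)
}

# noiseless series on the cumulative curve of `params`
noiseless_series <- function(params, n = 15, t_lo = NULL, t_hi = NULL) {
  if (is.null(t_lo)) t_lo <- params$x_min + 0.05 * (params$x_max - params$x_min)
  if (is.null(t_hi)) t_hi <- params$x_min + 0.95 * (params$x_max - params$x_min)
  times <- seq(t_lo, t_hi, length.out = n)
  growth_series(times, growth_cumulative(times, params), label = "noiseless")
}

# minimal stand-in fit for compare_models arithmetic checks
fake_fit <- function(model, rmse, n = 10, label = "fake") {
  structure(list(model = model,
                 params = growth_params(1, 1, 0, 10,
                                        delta = if (model == "BE") 1 else 2),
                 rss = rmse^2 * n, rmse = rmse, n = n, converged = TRUE,
                 n_restarts_used = 1L, seed = 1L,
                 series = growth_series(seq_len(n), rep(1, n), label = label)),
            class = "growth_fit")
}
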