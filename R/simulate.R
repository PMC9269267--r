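#' Simulation design for synthetic growth trajectories
#'
#' Describes how to generate a growth series with known ground truth: the
#' true parameter set, the sampling schedule, the number of replicate
#' individuals per sampling date, and the observation-noise model.
#'
#' @param params True [growth_params()] generating the data.
#' @param times Sampling schedule (non-negative times).
#' @param replicates_per_time Replicate individuals measured at each time
#'   (default 1).
#' @param noise_model `"additive_gaussian"` (noise in size units) or
#'   `"multiplicative_lognormal"` (noise as a relative factor).
#' @param noise_scale Noise magnitude: the Gaussian standard deviation in
#'   size units, or the log-normal sigma (dimensionless).  If `NULL`, the
#'   additive default is 2% of the asymptotic size, emulating measurement
#'   scatter in field biomass data; the multiplicative default is 0.02.
#' @param seed Integer seed; the simulation is reproducible given it.
#' @return An object of class `"simulation_design"`.
#' @seealso [design_crops_like()], [design_bamboo_like()] for the two
#'   canonical field designs.
#' @export
simulation_design <- function(params, times, replicates_per_time = 1L,
                              noise_model = c("additive_gaussian",
                                              "multiplicative_lognormal"),
                              noise_scale = NULL, seed = 1L) {
  params <- as_growth_params(params)
  noise_model <- match.arg(noise_model)
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative", call. = FALSE)
  replicates_per_time <- as.integer(replicates_per_time)
  if (replicates_per_time < 1L) stop("'replicates_per_time' must be >= 1", call. = FALSE)
  if (is.null(noise_scale)) {
    noise_scale <- if (noise_model == "additive_gaussian")
      0.02 * growth_cumulative(params$x_max, params) else 0.02
  }
  if (!is.finite(noise_scale) || noise_scale < 0)
    stop("'noise_scale' must be non-negative", call. = FALSE)
  structure(list(params = params, times = times,
                 replicates_per_time = replicates_per_time,
                 noise_model = noise_model, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Canonical crop-like simulation design
#'
#' Fifteen sampling dates every five days from day 14 to day 84 after
#' sowing, with 20 replicate individuals per date -- the structure of a
#' season-long destructive biomass survey of annual crops.
#'
#' @param params True [growth_params()]; the default is a mildly
#'   left-skewed rate curve with the end of growth just beyond the last
#'   sampling date and an asymptotic dry mass of roughly 150 size units
#'   (grams, on the crop reading).
#' @inheritParams simulation_design
#' @return A `"simulation_design"`.
#' @export
design_crops_like <- function(params = growth_params(a = 6e-6, m = 3,
                                                     x_min = 0, x_max = 90,
                                                     delta = 1.4),
                              noise_scale = NULL, seed = 1L) {
  simulation_design(params, times = seq(14, 84, by = 5),
                    replicates_per_time = 20L,
                    noise_model = "additive_gaussian",
                    noise_scale = noise_scale, seed = seed)
}

#' Canonical bamboo-like simulation design
#'
#' Daily height measurements for the first 30 days after shoot emergence,
#' then every three days -- the structure of repeated height surveys of
#' fast-extending bamboo shoots, with a single measured culm per date.
#'
#' @inheritParams design_crops_like
#' @return A `"simulation_design"`.
#' @export
design_bamboo_like <- function(params = growth_params(a = 0.023, m = 2,
                                                      x_min = 0, x_max = 50,
                                                      delta = 0.8),
                               noise_scale = NULL, seed = 1L) {
  simulation_design(params, times = c(0:30, seq(33, 60, by = 3)),
                    replicates_per_time = 1L,
                    noise_model = "additive_gaussian",
                    noise_scale = noise_scale, seed = seed)
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("Simulation design: %d times x %d replicates, %s noise (scale %g), seed %d\n",
              length(x$times), x$replicates_per_time, x$noise_model,
              x$noise_scale, x$seed))
  print(x$params)
  invisible(x)
}

#' Simulate a growth series from a design
#'
#' Sizes are the cumulative growth curve at each scheduled time plus noise
#' per the design's noise model; negative simulated sizes are clamped to
#' zero (a destructive biomass measurement cannot be negative).
#'
#' @param design A [simulation_design()].
#' @param label Label for the generated series.
#' @return A [growth_series()] with `length(times) * replicates_per_time`
#'   observations.
#' @examples
#' d <- design_crops_like(seed = 7)
#' s <- simulate_growth_series(d)
#' @export
simulate_growth_series <- function(design, label = "simulated") {
  if (!inherits(design, "simulation_design"))
    stop("'design' must be a simulation_design", call. = FALSE)
  mu_u <- growth_cumulative(design$times, design$params)
  times <- rep(design$times, each = design$replicates_per_time)
  mu <- rep(mu_u, each = design$replicates_per_time)
  sizes <- with_seed(design$seed, {
    if (design$noise_model == "additive_gaussian")
      mu + stats::rnorm(length(mu), 0, design$noise_scale)
    else
      mu * stats::rlnorm(length(mu), 0, design$noise_scale)
  })
  growth_series(times, pmax(sizes, 0), label = label)
}

#' Simulate an ovate leaf outline with known half-width parameters
#'
#' Builds a closed planar outline whose half-width at position `x` along
#' the length axis is the MBE rate curve: `+rate_mbe(x; upper)` above the
#' axis and `-rate_mbe(x; lower)` below it.  The outline is axially
#' symmetric exactly when the two parameter sets coincide.  Gaussian noise
#' of standard deviation `noise_scale` (length units) is added to the
#' widths of interior points; the base and apex stay on the axis and the
#' outline is closed (first point repeated last).
#'
#' @param upper,lower [growth_params()] for the two half-widths; they must
#'   share `x_min` (the base) and `x_max` (the apex).
#' @param n_points Approximate number of outline points (at least 20).
#' @param noise_scale Noise standard deviation in length units.
#' @param seed Integer seed.
#' @return A [leaf_outline()], traced base -> apex along the upper margin
#'   and back along the lower margin.
#' @export
simulate_leaf_outline <- function(upper, lower = upper, n_points = 120L,
                                  noise_scale = 0, seed = 1L) {
  upper <- as_growth_params(upper); lower <- as_growth_params(lower)
  if (upper$x_min != lower$x_min || upper$x_max != lower$x_max)
    stop("'upper' and 'lower' must share x_min (base) and x_max (apex)",
         call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 20L) stop("'n_points' must be at least 20", call. = FALSE)
  if (!is.finite(noise_scale) || noise_scale < 0)
    stop("'noise_scale' must be non-negative", call. = FALSE)

  n_half <- n_points %/% 2L + 1L
  xs <- seq(upper$x_min, upper$x_max, length.out = n_half)
  up <- rate_mbe(xs, upper)
  lo <- -rate_mbe(xs, lower)
  noise <- with_seed(seed, stats::rnorm(2L * (n_half - 2L), 0, noise_scale))
  interior <- 2:(n_half - 1L)
  up[interior] <- up[interior] + noise[seq_along(interior)]
  lo[interior] <- lo[interior] + noise[length(interior) + seq_along(interior)]
  # base -> apex along the upper margin, apex -> base along the lower
  px <- c(xs, rev(xs[interior]), xs[1L])
  py <- c(up, rev(lo[interior]), up[1L])
  leaf_outline(cbind(x = px, y = py), closed = TRUE)
}
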