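#' Briere growth-rate function
#'
#' Evaluates the Briere equation (BE) as a time-dependent growth rate,
#' \deqn{f(x) = a\,x\,(x - x_{min})\,(x_{max} - x)^{1/m},}
#' with \eqn{f(x) = 0} for `x < x_min` or `x > x_max`.  The same functional
#' form describes temperature-dependent development rates when `x` is read
#' as temperature and the support edges as thermal thresholds; here it is
#' used on the time axis, where its integral is a sigmoid growth curve.
#'
#' @param x Numeric vector of times.
#' @param params A [growth_params()] set; `delta` is ignored (the BE is the
#'   `delta = 1` member of the family).
#' @return Numeric vector of rates, non-negative, zero outside
#'   `[x_min, x_max]`.
#' @examples
#' p <- growth_params(a = 0.01, m = 3, x_min = 0, x_max = 35)
#' rate_be(c(0, 10, 35, 40), p)
#' @export
rate_be <- function(x, params) {
  params <- as_growth_params(params)
  br <- be_bracket(x, params)
  params$a * br
}

#' Modified Briere growth-rate function
#'
#' Evaluates the modified Briere equation (MBE),
#' \deqn{f(x) = a\,\left| x\,(x - x_{min})\,(x_{max} - x)^{1/m}\right|^{\delta},}
#' zero outside `[x_min, x_max]`.  The extra elasticity exponent `delta`
#' reshapes the curvature of the rate curve (and hence of its integrated
#' sigmoid) without moving the support or the location of the peak; at
#' `delta = 1` the MBE coincides with [rate_be()] exactly.
#'
#' @inheritParams rate_be
#' @param params A [growth_params()] set; `delta` is the elasticity
#'   exponent.
#' @return Numeric vector of rates, non-negative, zero outside
#'   `[x_min, x_max]`.
#' @examples
#' p <- growth_params(a = 0.01, m = 3, x_min = 0, x_max = 35, delta = 2)
#' rate_mbe(10, p)
#' rate_mbe(10, growth_params(0.01, 3, 0, 35, delta = 1)) == rate_be(10, p)
#' @export
rate_mbe <- function(x, params) {
  params <- as_growth_params(params)
  if (params$delta == 1) return(params$a * be_bracket(x, params))
  br <- be_bracket(x, params)
  r <- params$a * abs(br)^params$delta
  # the support clamp takes precedence over the absolute value
  r[x < params$x_min | x > params$x_max] <- 0
  r
}

# The common bracket x (x - x_min) (x_max - x)^(1/m), clamped to 0 outside
# the support.  (x_max - x)^(1/m) is only evaluated on x <= x_max so a
# fractional exponent never sees a negative base.
be_bracket <- function(x, params) {
  out <- numeric(length(x))
  inside <- is.finite(x) & x >= params$x_min & x <= params$x_max
  xi <- x[inside]
  out[inside] <- xi * (xi - params$x_min) * (params$x_max - xi)^(1 / params$m)
  out[!is.finite(x)] <- NA_real_
  out
}

#' Time of maximum growth rate
#'
#' Returns the unique time in `(x_min, x_max)` at which the rate curve
#' peaks.  The MBE is a positive monotone transform of the BE bracket, so
#' the peak location does not depend on `delta`; it is the interior root of
#' \deqn{(2m+1)x^2 - \left[(1+m)x_{min} + 2m\,x_{max}\right]x + m\,x_{min}x_{max} = 0,}
#' which for `x_min = 0` reduces to \eqn{2m\,x_{max}/(2m+1)}.
#'
#' @param params A [growth_params()] set.
#' @return The peak time, a scalar in `(x_min, x_max)`.
#' @examples
#' peak_growth_time(growth_params(0.01, 3, 0, 35))  # 30
#' @export
peak_growth_time <- function(params) {
  params <- as_growth_params(params)
  A <- 2 * params$m + 1
  B <- -((1 + params$m) * params$x_min + 2 * params$m * params$x_max)
  C <- params$m * params$x_min * params$x_max
  # stable quadratic roots
  disc <- sqrt(B^2 - 4 * A * C)
  q <- -0.5 * (B + sign(B + (B == 0)) * disc)
  roots <- c(q / A, if (q != 0) C / q else numeric(0))
  inside <- roots[roots > params$x_min & roots < params$x_max]
  if (length(inside) == 0L)
    stop("no interior peak found; parameter set is degenerate", call. = FALSE)
  # both roots can sit inside only in degenerate limits; take the argmax
  if (length(inside) > 1L)
    inside <- inside[which.max(rate_mbe(inside, params))]
  inside
}

#' Skew direction of the growth-rate curve
#'
#' Classifies the rate curve by comparing the peak time to the midpoint of
#' the support.  Following the convention of thermal biology (where rate
#' curves are "usually left-skewed"), a peak in the right half of the
#' support -- a long left tail -- is called `"left_skewed"`; a peak in the
#' left half is `"right_skewed"`; a peak at the midpoint (within
#' `1e-9 * (x_max - x_min)`) is `"symmetric"`.  The classification is
#' independent of `delta`.
#'
#' @param params A [growth_params()] set.
#' @return One of `"left_skewed"`, `"right_skewed"`, `"symmetric"`.
#' @examples
#' skew_direction(growth_params(0.01, 3, 0, 35))  # peak 30 > midpoint 17.5
#' @export
skew_direction <- function(params) {
  params <- as_growth_params(params)
  peak <- peak_growth_time(params)
  mid <- (params$x_min + params$x_max) / 2
  tol <- 1e-9 * (params$x_max - params$x_min)
  if (abs(peak - mid) <= tol) "symmetric"
  else if (peak > mid) "left_skewed"
  else "right_skewed"
}
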