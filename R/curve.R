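#' Sigmoid growth curve from an integrated rate model
#'
#' Constructs the cumulative (sigmoid) growth curve
#' \deqn{y(x) = \int_{x_{min}}^{x} f(t)\,dt}
#' for a BE/MBE rate function `f`, with `y = 0` below `x_min` and a plateau
#' at the total integral above `x_max`.  The BE sigmoid has a closed form
#' only in special cases; both members of the family are integrated
#' numerically here with adaptive quadrature.
#'
#' @param params A [growth_params()] set.
#' @param rel.tol Relative quadrature tolerance (default `1e-9`).  Near
#'   `x_max` the integrand has an integrable power singularity in its
#'   derivative when `delta/m < 1`; the adaptive scheme resolves it.
#' @return An object of class `"growth_curve"` holding the parameters, the
#'   tolerance, and a lazily cached total integral over the support.
#' @examples
#' cv <- growth_curve(growth_params(0.01, 3, 0, 35, delta = 2))
#' predict(cv, c(0, 10, 20, 35, 50))
#' @seealso [growth_cumulative()] for a one-shot functional interface.
#' @export
growth_curve <- function(params, rel.tol = 1e-9) {
  params <- as_growth_params(params)
  stopifnot(is.numeric(rel.tol), rel.tol > 0)
  obj <- list(params = params, rel.tol = rel.tol, cache = new.env(parent = emptyenv()))
  class(obj) <- "growth_curve"
  obj
}

#' Evaluate the cumulative growth curve
#'
#' Piecewise definition: `0` for `x < x_min`; the integral of the rate from
#' `x_min` to `x` on the support; the total integral (the asymptotic size)
#' for `x > x_max`.  A vector of times is evaluated by accumulating
#' panel-wise sub-integrals between consecutive sorted values, so a whole
#' trajectory costs little more than its largest time.
#'
#' @param x Numeric vector of times (any order).
#' @param curve A `"growth_curve"` object, or a [growth_params()] set (a
#'   default-tolerance curve is built on the fly).
#' @param rel.tol Optional override of the curve's quadrature tolerance.
#' @return Numeric vector of cumulative sizes, non-decreasing in `x`.
#' @examples
#' p <- growth_params(0.01, 3, 0, 35)  # BE, x_min = 0
#' # total integral has the Beta-function closed form a x_max^(3+1/m) B(3, 1+1/m)
#' growth_cumulative(35, p)
#' 0.01 * 35^(3 + 1/3) * beta(3, 1 + 1/3)
#' @export
growth_cumulative <- function(x, curve, rel.tol = NULL) {
  if (!inherits(curve, "growth_curve")) curve <- growth_curve(curve)
  if (is.null(rel.tol)) rel.tol <- curve$rel.tol
  p <- curve$params
  stopifnot(is.numeric(x), all(is.finite(x)))

  out <- numeric(length(x))
  ord <- order(x)
  xs <- x[ord]
  xc <- pmin(pmax(xs, p$x_min), p$x_max)
  # split at the interior root x = 0 (if any) so the adaptive rule never
  # integrates across a point where the integrand loses smoothness
  bounds <- sort(unique(c(p$x_min, xc,
                          if (p$x_min < 0 && p$x_max > 0 && any(xc > 0)) 0)))
  total <- rep(NA_real_, length(bounds))
  acc <- 0
  for (i in seq_along(bounds)[-1]) {
    acc <- acc + quad_panel(p, bounds[i - 1L], bounds[i], rel.tol, bounds[i])
    total[i] <- acc
  }
  total[1L] <- 0
  vals <- total[match(xc, bounds)]
  # plateau: cache the full integral once evaluation passes x_max
  if (any(xs > p$x_max)) {
    ct <- curve_total(curve, rel.tol)
    vals[xc >= p$x_max] <- ct
  }
  out[ord] <- vals
  out
}

# total integral over the support, cached lazily on the curve object
curve_total <- function(curve, rel.tol = curve$rel.tol) {
  if (is.null(curve$cache$total)) {
    p <- curve$params
    cuts <- sort(unique(c(p$x_min, if (p$x_min < 0 && p$x_max > 0) 0,
                          peak_growth_time(p), p$x_max)))
    curve$cache$total <- sum(vapply(seq_along(cuts)[-1], function(i)
      quad_panel(p, cuts[i - 1L], cuts[i], rel.tol, p$x_max), numeric(1)))
  }
  curve$cache$total
}

# one adaptive sub-integral; errors name the requested evaluation point
quad_panel <- function(p, lo, hi, rel.tol, at_x) {
  if (hi <= lo) return(0)
  res <- tryCatch(
    stats::integrate(function(t) rate_raw(t, p), lo, hi,
                     rel.tol = rel.tol, subdivisions = 500L),
    error = function(e) e)
  if (inherits(res, "error") || res$message != "OK")
    stop(sprintf("quadrature failed to converge at x = %g (%s)", at_x,
                 if (inherits(res, "error")) conditionMessage(res) else res$message),
         call. = FALSE)
  res$value
}

# rate without re-validation, for quadrature/fitting hot paths
rate_raw <- function(x, p) {
  br <- be_bracket(x, p)
  if (p$delta == 1) p$a * br else p$a * abs(br)^p$delta
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("Sigmoid growth curve (integrated ",
      if (isTRUE(all.equal(x$params$delta, 1))) "BE" else "MBE", " rate)\n", sep = "")
  print(x$params)
  cat(sprintf("  quadrature rel.tol = %g\n", x$rel.tol))
  if (!is.null(x$cache$total))
    cat(sprintf("  asymptotic size = %g\n", x$cache$total))
  invisible(x)
}

#' @export
#' @rdname growth_curve
#' @param object A `"growth_curve"` object.
#' @param type `"cumulative"` for the sigmoid curve, `"rate"` for the
#'   underlying rate function.
#' @param ... Unused.
predict.growth_curve <- function(object, x, type = c("cumulative", "rate"), ...) {
  type <- match.arg(type)
  if (type == "rate") rate_mbe(x, object$params)
  else growth_cumulative(x, object)
}

#' @export
plot.growth_curve <- function(x, n = 301, which = c("cumulative", "rate"), ...) {
  which <- match.arg(which)
  p <- x$params
  pad <- 0.05 * (p$x_max - p$x_min)
  xx <- seq(p$x_min - pad, p$x_max + pad, length.out = n)
  if (which == "rate") {
    graphics::plot(xx, rate_mbe(xx, p), type = "l", xlab = "time",
                   ylab = "growth rate", ...)
  } else {
    graphics::plot(xx, growth_cumulative(xx, x), type = "l", xlab = "time",
                   ylab = "cumulative size", ...)
  }
  invisible(x)
}

# ---- fixed-order Gauss-Legendre engine (fitting hot path) ----------------

.gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_cache[[key]]
}

# Cumulative curve at sorted unique times via panel-wise Gauss-Legendre.
# Panels touching a support edge use the substitution x = edge -/+ s^2 to
# soften the integrable power singularity of the integrand's derivative.
cumulative_gl <- function(x, p, n_nodes = 24L) {
  rule <- gl_rule(n_nodes)
  xc <- pmin(pmax(x, p$x_min), p$x_max)
  # points where the integrand's derivative can blow up: the support edges
  # and, when the support straddles it, the interior root at x = 0
  sing <- c(p$x_min, p$x_max,
            if (p$x_min < 0 && p$x_max > 0) 0)
  bounds <- sort(unique(c(xc, sing)))
  bounds <- bounds[bounds >= p$x_min & bounds <= p$x_max]
  nb <- length(bounds)
  if (nb <= 1L) return(numeric(length(x)))
  lo <- bounds[-nb]; hi <- bounds[-1L]
  lo_sing <- lo %in% sing; hi_sing <- hi %in% sing
  plain <- !lo_sing & !hi_sing
  inc <- numeric(nb - 1L)
  if (any(plain)) {
    h <- hi[plain] - lo[plain]
    X <- rep(lo[plain], each = n_nodes) + rep(h, each = n_nodes) * rule$x
    inc[plain] <- h * colSums(matrix(rule$w * rate_raw(X, p), nrow = n_nodes))
  }
  for (i in which(!plain)) {
    if (lo_sing[i] && hi_sing[i]) {
      mid <- 0.5 * (lo[i] + hi[i])
      inc[i] <- gl_edge(p, lo[i], mid, rule, left = TRUE) +
        gl_edge(p, mid, hi[i], rule, left = FALSE)
    } else if (lo_sing[i]) {
      inc[i] <- gl_edge(p, lo[i], hi[i], rule, left = TRUE)
    } else {
      inc[i] <- gl_edge(p, lo[i], hi[i], rule, left = FALSE)
    }
  }
  cum <- c(0, cumsum(inc))
  cum[match(xc, bounds)]
}

# integral over [lo, hi] with a square-root substitution at one edge
gl_edge <- function(p, lo, hi, rule, left) {
  smax <- sqrt(hi - lo)
  s <- smax * rule$x
  xx <- if (left) lo + s^2 else hi - s^2
  smax * sum(rule$w * (2 * s * rate_raw(xx, p)))
}
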