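#' Growth-model parameter set
#'
#' Bundles the five constants of the Briere-family rate models: the scale
#' constant `a`, the shape exponent `m`, the start and end times of growth
#' `x_min` and `x_max`, and the elasticity exponent `delta`.  `delta = 1`
#' is exactly the original Briere equation (BE); any other positive value
#' gives the modified Briere equation (MBE).
#'
#' @param a Positive scale constant (size per time, after integration).
#' @param m Positive shape exponent (dimensionless).  The right support
#'   edge enters as `(x_max - x)^(1/m)`, so larger `m` makes the rate
#'   curve drop more abruptly at the end of growth.
#' @param x_min Start time of growth.  The rate is exactly zero for
#'   `x < x_min`.
#' @param x_max End time of growth; must exceed `x_min`.  The rate is
#'   exactly zero for `x > x_max`.
#' @param delta Positive elasticity exponent (dimensionless); `1` recovers
#'   the BE.
#'
#' @return An object of class `"growth_params"`: a named list with
#'   components `a`, `m`, `x_min`, `x_max`, `delta`.
#' @examples
#' p <- growth_params(a = 0.01, m = 3, x_min = 0, x_max = 35)
#' p
#' @seealso [rate_be()], [rate_mbe()], [growth_curve()]
#' @export
growth_params <- function(a, m, x_min, x_max, delta = 1) {
  p <- list(a = as.numeric(a), m = as.numeric(m),
            x_min = as.numeric(x_min), x_max = as.numeric(x_max),
            delta = as.numeric(delta))
  class(p) <- "growth_params"
  validate_growth_params(p)
  p
}

#' Validate a growth-model parameter set
#'
#' Checks the domain constraints `a > 0`, `m > 0`, `delta > 0` and
#' `x_max > x_min`, all finite.  Called by every function that consumes a
#' parameter set; exposed so user code can validate early.
#'
#' @param p A `"growth_params"` object or a named list coercible to one.
#' @return `p`, invisibly, as a validated `"growth_params"` object.
#' @export
validate_growth_params <- function(p) {
  if (!inherits(p, "growth_params")) {
    need <- c("a", "m", "x_min", "x_max")
    if (!is.list(p) || !all(need %in% names(p)))
      stop("parameter set must contain a, m, x_min, x_max (and optionally delta)",
           call. = FALSE)
    if (is.null(p$delta)) p$delta <- 1
    p <- structure(p[c("a", "m", "x_min", "x_max", "delta")],
                   class = "growth_params")
  }
  v <- unlist(p[c("a", "m", "x_min", "x_max", "delta")])
  if (!all(is.finite(v)))
    stop("growth parameters must all be finite", call. = FALSE)
  if (p$a <= 0) stop("'a' must be positive", call. = FALSE)
  if (p$m <= 0) stop("'m' must be positive", call. = FALSE)
  if (p$delta <= 0) stop("'delta' must be positive", call. = FALSE)
  if (p$x_max <= p$x_min)
    stop("'x_max' must be greater than 'x_min'", call. = FALSE)
  invisible(p)
}

#' @export
print.growth_params <- function(x, digits = 6, ...) {
  kind <- if (isTRUE(all.equal(x$delta, 1))) "BE (delta = 1)" else "MBE"
  cat("Growth-model parameters [", kind, "]\n", sep = "")
  cat(sprintf("  a = %.*g, m = %.*g, x_min = %.*g, x_max = %.*g, delta = %.*g\n",
              digits, x$a, digits, x$m, digits, x$x_min,
              digits, x$x_max, digits, x$delta))
  invisible(x)
}

#' @export
as.list.growth_params <- function(x, ...) unclass(x)

# internal: coerce + validate in one step
as_growth_params <- function(p) {
  validate_growth_params(p)
}
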