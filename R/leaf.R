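#' Planar leaf outline
#'
#' An ordered trace of the leaf boundary as (x, y) coordinates in length
#' units (e.g. cm from a scanned lamina).
#'
#' @param points Two-column numeric matrix or data frame with columns
#'   `x`, `y`; at least 20 points, finite.
#' @param closed Whether the first point equals the last.  If `NA`
#'   (default) it is detected.
#' @return An object of class `"leaf_outline"`.
#' @export
leaf_outline <- function(points, closed = NA) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("'points' must have two columns (x, y)", call. = FALSE)
  colnames(pts) <- c("x", "y")
  storage.mode(pts) <- "double"
  if (nrow(pts) < 20L) stop("a leaf outline needs at least 20 points", call. = FALSE)
  if (!all(is.finite(pts))) stop("outline coordinates must be finite", call. = FALSE)
  if (is.na(closed))
    closed <- isTRUE(all.equal(pts[1L, ], pts[nrow(pts), ], tolerance = 1e-12))
  structure(list(points = pts, closed = isTRUE(closed)), class = "leaf_outline")
}

#' @export
print.leaf_outline <- function(x, ...) {
  cat(sprintf("Leaf outline: %d points (%s)\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' @export
plot.leaf_outline <- function(x, ...) {
  graphics::plot(x$points, type = "l", asp = 1, xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Register a leaf outline onto its length axis
#'
#' Rigidly moves the outline so the leaf base sits at the origin and the
#' apex on the positive x-axis, making the half-widths single-valued
#' functions of the position along the length axis.  The length axis is
#' the segment between the two boundary points realizing the maximum
#' pairwise distance.  Orientation: the MBE half-width profile always
#' peaks in the apical half of its support, so the axis endpoint on the
#' far side of the outline's width-weighted centroid becomes the base and
#' the wide section faces the apex.  Registration is an isometry
#' (translation + rotation) and is idempotent.
#'
#' @param outline A [leaf_outline()].
#' @return The registered [leaf_outline()], with attribute
#'   `"registration"`: a list with `translation` (applied to the raw
#'   coordinates first) and `angle` (rotation, radians).
#' @export
register_leaf <- function(outline) {
  if (!inherits(outline, "leaf_outline")) outline <- leaf_outline(outline)
  pts <- outline$points
  if (outline$closed) pts <- pts[-nrow(pts), , drop = FALSE]
  d <- as.matrix(stats::dist(pts))
  ij <- arrayInd(which.max(d), dim(d))
  len <- d[ij]
  if (len <= 0) stop("degenerate outline: zero length", call. = FALSE)
  p1 <- pts[ij[1L], ]; p2 <- pts[ij[2L], ]

  orient <- function(base, apex) {
    ang <- -atan2(apex[2L] - base[2L], apex[1L] - base[1L])
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
    q <- sweep(pts, 2L, base) %*% t(R)
    list(pts = q, translation = -base, angle = ang)
  }
  cand <- orient(p1, p2)
  w <- abs(cand$pts[, 2L])
  if (sum(w) <= len * 1e-9)
    stop("degenerate outline: collinear points enclose no area", call. = FALSE)
  centroid_x <- sum(w * cand$pts[, 1L]) / sum(w)
  # wide section toward the apex: flip if the width centroid sits in the
  # basal half
  if (centroid_x < len / 2) cand <- orient(p2, p1)

  q <- cand$pts
  if (outline$closed) q <- rbind(q, q[1L, , drop = FALSE])
  out <- leaf_outline(q, closed = outline$closed)
  attr(out, "registration") <- list(translation = cand$translation,
                                    angle = cand$angle, length = len)
  out
}

#' Fit MBE half-width curves to a registered leaf outline
#'
#' Splits the boundary points of a registered outline into the upper
#' (`y >= 0`) and lower (`y < 0`) margins and fits an MBE rate curve to
#' each half-width by Nelder-Mead least squares on the vertical residuals,
#' with `x_min` fixed at 0 (the base) and `x_max` fixed at the leaf length
#' (the apex), leaving `(a, m, delta)` free per half.  With
#' `symmetric = TRUE` a single parameter set is fitted to `|y|` of all
#' points; since the symmetric model is the constrained case, its RSS can
#' never be below the asymmetric fit's.
#'
#' @param outline A [leaf_outline()]; registered with [register_leaf()]
#'   (an unregistered outline is registered on the fly).
#' @param symmetric Fit one shared parameter set to both margins?
#' @param seed Integer seed (restart jitter; the default grid is
#'   deterministic).
#' @param n_restarts Optimizer restarts per half (default: the 9-point
#'   starting grid over `m` and `delta`).
#' @return An object of class `"leaf_fit"` with `upper_params`,
#'   `lower_params` (identical when `symmetric`), `rss`, `rmse` over all
#'   boundary points, `leaf_length`, and the registration record.
#' @examples
#' up <- growth_params(0.003, 3, 0, 10, delta = 1.5)
#' lo <- growth_params(0.004, 2.5, 0, 10, delta = 1.2)
#' out <- simulate_leaf_outline(up, lo, n_points = 80)
#' fit <- fit_leaf(out)
#' @export
fit_leaf <- function(outline, symmetric = FALSE, seed = 1L, n_restarts = NULL) {
  if (!inherits(outline, "leaf_outline")) outline <- leaf_outline(outline)
  reg <- attr(outline, "registration")
  if (is.null(reg)) {
    outline <- register_leaf(outline)
    reg <- attr(outline, "registration")
  }
  pts <- outline$points
  if (outline$closed) pts <- pts[-nrow(pts), , drop = FALSE]
  len <- max(pts[, 1L])
  upper <- pts[pts[, 2L] >= 0, , drop = FALSE]
  lower <- pts[pts[, 2L] < 0, , drop = FALSE]
  if (nrow(upper) < 5L || nrow(lower) < 5L)
    stop(sprintf("too few points per margin (upper %d, lower %d; need 5 each)",
                 nrow(upper), nrow(lower)), call. = FALSE)

  if (symmetric) {
    f <- fit_half_width(pts[, 1L], abs(pts[, 2L]), len, seed, n_restarts)
    up_p <- lo_p <- f$params
    rss <- f$rss
  } else {
    fu <- fit_half_width(upper[, 1L], upper[, 2L], len, seed, n_restarts)
    fl <- fit_half_width(lower[, 1L], -lower[, 2L], len, seed, n_restarts)
    up_p <- fu$params; lo_p <- fl$params
    rss <- fu$rss + fl$rss
  }
  structure(list(upper_params = up_p, lower_params = lo_p,
                 rss = rss, rmse = compute_rmse(rss, nrow(pts)),
                 n = nrow(pts), leaf_length = len, symmetric = symmetric,
                 registration = reg, outline = outline),
            class = "leaf_fit")
}

# least-squares MBE half-width fit with x_min = 0, x_max = len fixed
fit_half_width <- function(x, w, len, seed, n_restarts) {
  obj <- function(th) {
    p <- list(a = exp(th[1L]), m = exp(th[2L]), x_min = 0, x_max = len,
              delta = exp(th[3L]))
    if (!all(is.finite(unlist(p)))) return(1e300)
    r <- sum((w - rate_raw(x, p))^2)
    if (is.finite(r)) r else 1e300
  }
  g <- expand.grid(m = c(1, 2, 4), delta = c(0.5, 1, 2), KEEP.OUT.ATTRS = FALSE)
  w_top <- max(w, 1e-12)
  starts <- t(vapply(seq_len(nrow(g)), function(i) {
    p1 <- list(a = 1, m = g$m[i], x_min = 0, x_max = len, delta = g$delta[i])
    peak <- rate_raw(peak_growth_time(p1), p1)
    c(log(if (peak > 0) w_top / peak else 1), log(g$m[i]), log(g$delta[i]))
  }, numeric(3L)))
  if (is.null(n_restarts)) n_restarts <- nrow(starts)
  if (n_restarts <= nrow(starts)) {
    starts <- starts[seq_len(n_restarts), , drop = FALSE]
  } else {
    extra <- with_seed(as.integer(seed), {
      base <- starts[1 + (seq_len(n_restarts - nrow(starts)) - 1L) %% nrow(starts), ,
                     drop = FALSE]
      base + matrix(stats::runif(length(base), log(0.8), log(1.2)), nrow(base))
    })
    starts <- rbind(starts, extra)
  }
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    f <- stats::optim(starts[r, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000L))
    if (is.null(best) || f$value < best$value) best <- f
  }
  params <- growth_params(exp(best$par[1L]), exp(best$par[2L]), 0, len,
                          exp(best$par[3L]))
  list(params = params, rss = best$value)
}

#' @export
print.leaf_fit <- function(x, digits = 6, ...) {
  cat(sprintf("MBE leaf-outline fit (%s margins), leaf length %.*g\n",
              if (x$symmetric) "symmetric" else "independent", digits,
              x$leaf_length))
  cat("  upper margin: "); print(x$upper_params, digits = digits)
  if (!x$symmetric) { cat("  lower margin: "); print(x$lower_params, digits = digits) }
  cat(sprintf("  n = %d boundary points, RSS = %.*g, RMSE = %.*g\n",
              x$n, digits, x$rss, digits, x$rmse))
  invisible(x)
}

#' @export
plot.leaf_fit <- function(x, n_grid = 200, ...) {
  plot(x$outline, col = "grey50", ...)
  xx <- seq(0, x$leaf_length, length.out = n_grid)
  graphics::lines(xx, rate_mbe(xx, x$upper_params), col = "red", lwd = 2)
  graphics::lines(xx, -rate_mbe(xx, x$lower_params), col = "red", lwd = 2)
  invisible(x)
}
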