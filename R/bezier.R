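# Cubic Bezier segments and composite curves: evaluation, derivatives,
# arc length, signed curvature, radius-of-curvature summaries, and
# join-continuity diagnostics.

# 24-point Gauss-Legendre rule on [0, 1], used for all arc-length quadrature.
.gl24 <- pracma::gaussLegendre(24, 0, 1)

#' Construct a cubic Bezier segment
#'
#' A cubic Bezier segment is determined by four control points: the curve
#' starts at `p0`, ends at `p3`, and the interior points `p1`, `p2` shape
#' its tangents and curvature.
#'
#' @param p0,p1,p2,p3 Numeric length-2 vectors `(x, y)`, in pixels.
#' @return An object of class `bezier_segment`: a 4 x 2 numeric matrix with
#'   columns `x`, `y`, one row per control point.
#' @examples
#' seg <- bezier_segment(c(0, 0), c(1, 0), c(2, 1), c(3, 1))
#' bezier_point(seg, 0.5)
#' @export
bezier_segment <- function(p0, p1, p2, p3) {
  cp <- rbind(p0, p1, p2, p3)
  if (!is.numeric(cp) || any(dim(cp) != c(4L, 2L)) || any(!is.finite(cp)))
    stop("a cubic Bezier segment needs four finite (x, y) control points")
  if (max(dist(cp)) == 0)
    stop("degenerate segment: all four control points coincide")
  dimnames(cp) <- list(c("p0", "p1", "p2", "p3"), c("x", "y"))
  structure(cp, class = "bezier_segment")
}

as_segment <- function(x) {
  if (inherits(x, "bezier_segment")) return(x)
  x <- as.matrix(x)
  bezier_segment(x[1, ], x[2, ], x[3, ], x[4, ])
}

#' Chain cubic Bezier segments into a composite curve
#'
#' Consecutive segments must share an endpoint: the last control point of
#' segment i is the first control point of segment i + 1 (within 1e-9 px).
#'
#' @param ... `bezier_segment` objects, or a single list of them.
#' @return An object of class `composite_bezier` (a list of segments).
#' @export
composite_bezier <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1]]) && !inherits(segs[[1]], "bezier_segment"))
    segs <- segs[[1]]
  if (length(segs) < 1L) stop("a composite curve needs at least one segment")
  segs <- lapply(segs, as_segment)
  if (length(segs) > 1L) {
    for (i in seq_len(length(segs) - 1L)) {
      gap <- sqrt(sum((segs[[i]][4, ] - segs[[i + 1L]][1, ])^2))
      if (gap > 1e-9)
        stop(sprintf("segments %d and %d do not share an endpoint (gap %.3g px)",
                     i, i + 1L, gap))
    }
  }
  structure(segs, class = "composite_bezier")
}

as_composite <- function(x) {
  if (inherits(x, "composite_bezier")) return(x)
  if (inherits(x, "bezier_segment")) return(composite_bezier(x))
  if (is.list(x)) return(composite_bezier(x))
  stop("cannot interpret input as a composite Bezier curve")
}

#' @export
print.composite_bezier <- function(x, ...) {
  cat(sprintf("Composite cubic Bezier curve: %d segment(s), arc length %.2f px\n",
              length(x), arc_length(x)))
  ends <- t(vapply(x, function(s) s[4, ], numeric(2)))
  cat(sprintf("  start (%.2f, %.2f) -> end (%.2f, %.2f)\n",
              x[[1]][1, 1], x[[1]][1, 2], ends[nrow(ends), 1], ends[nrow(ends), 2]))
  invisible(x)
}

# Bernstein-basis evaluation; t may be a vector. Returns n x 2 matrix.
bezier_eval_mat <- function(seg, t) {
  u <- 1 - t
  b <- cbind(u^3, 3 * u^2 * t, 3 * u * t^2, t^3)
  b %*% unclass(seg)
}

bezier_d1_mat <- function(seg, t) {
  u <- 1 - t
  d <- 3 * rbind(seg[2, ] - seg[1, ], seg[3, ] - seg[2, ], seg[4, ] - seg[3, ])
  cbind(u^2, 2 * u * t, t^2) %*% d
}

bezier_d2_mat <- function(seg, t) {
  d2 <- 6 * rbind(seg[1, ] - 2 * seg[2, ] + seg[3, ],
                  seg[2, ] - 2 * seg[3, ] + seg[4, ])
  cbind(1 - t, t) %*% d2
}

#' Evaluate a cubic Bezier segment
#'
#' @param segment A `bezier_segment`.
#' @param t Curve parameter(s) in `[0, 1]`.
#' @return A numeric length-2 vector `(x, y)` for scalar `t`, otherwise a
#'   matrix with one row per parameter value.
#' @export
bezier_point <- function(segment, t) {
  segment <- as_segment(segment)
  if (any(t < 0 | t > 1)) stop("curve parameter t must lie in [0, 1]")
  out <- bezier_eval_mat(segment, t)
  if (length(t) == 1L) c(x = unname(out[1, 1]), y = unname(out[1, 2]))
  else out
}

#' Signed curvature of a cubic Bezier segment
#'
#' Computes kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2) at the given
#' parameter values. The sign follows the usual orientation convention:
#' kappa > 0 where the curve turns counterclockwise when traversed from
#' `p0` to `p3` in y-up coordinates. For the S-lines studied here, drawn
#' bottom-to-top, the convex upper arc has positive curvature.
#'
#' @param segment A `bezier_segment`.
#' @param t Parameter value(s) in `[0, 1]`.
#' @return Signed curvature in 1/px (vectorized over `t`).
#' @export
bezier_curvature <- function(segment, t) {
  segment <- as_segment(segment)
  if (any(t < 0 | t > 1)) stop("curve parameter t must lie in [0, 1]")
  d1 <- bezier_d1_mat(segment, t)
  d2 <- bezier_d2_mat(segment, t)
  sp <- sqrt(rowSums(d1^2))
  if (any(sp < 1e-12))
    stop("degenerate tangent: first derivative vanishes at a requested t")
  as.numeric((d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / sp^3)
}

seg_speed <- function(seg, t) sqrt(rowSums(bezier_d1_mat(seg, t)^2))

# Arc length of one segment from 0 to t1 (Gauss-Legendre, 24 points).
seg_arclen <- function(seg, t1 = 1) {
  if (t1 <= 0) return(0)
  t1 * sum(.gl24$w * seg_speed(seg, t1 * .gl24$x))
}

seg_lengths <- function(curve) vapply(curve, seg_arclen, numeric(1))

#' Arc length of a composite Bezier curve
#'
#' Numerically integrated speed, per segment, by 24-point Gauss-Legendre
#' quadrature. Optionally stops at a global parameter `up_to`: a value in
#' `[0, n_segments]` whose integer part selects the segment and fractional
#' part the local parameter.
#'
#' @param curve A `composite_bezier` (or a single segment).
#' @param up_to Optional global parameter at which to stop.
#' @return Length in px.
#' @export
arc_length <- function(curve, up_to = NULL) {
  curve <- as_composite(curve)
  n <- length(curve)
  if (is.null(up_to)) return(sum(seg_lengths(curve)))
  if (up_to < 0 || up_to > n) stop("up_to must lie in [0, n_segments]")
  k <- min(floor(up_to), n - 1)
  part <- if (k > 0) sum(seg_lengths(curve)[seq_len(k)]) else 0
  part + seg_arclen(curve[[k + 1L]], up_to - k)
}

# Evaluate a composite at global parameters u in [0, n]; returns m x 2 matrix.
composite_eval <- function(curve, u) {
  n <- length(curve)
  seg <- pmin(floor(u), n - 1) + 1L
  tloc <- u - (seg - 1L)
  out <- matrix(0, length(u), 2)
  for (i in unique(seg)) {
    idx <- seg == i
    out[idx, ] <- bezier_eval_mat(curve[[i]], tloc[idx])
  }
  colnames(out) <- c("x", "y")
  out
}

composite_curvature <- function(curve, u) {
  n <- length(curve)
  seg <- pmin(floor(u), n - 1) + 1L
  tloc <- u - (seg - 1L)
  out <- numeric(length(u))
  for (i in unique(seg)) {
    idx <- seg == i
    out[idx] <- bezier_curvature(curve[[i]], tloc[idx])
  }
  out
}

# Invert arc length: global parameters u such that arc_length(curve, u) = s.
# Per segment, a dense cumulative-trapezoid table of the speed is inverted
# by monotone interpolation; the table is rescaled to the quadrature arc
# length so segment boundaries are exact.
arclen_to_param <- function(curve, s, seg_len = seg_lengths(curve),
                            grid_n = 1025) {
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(curve))
  u <- numeric(length(s))
  tg <- seq(0, 1, length.out = grid_n)
  dt <- 1 / (grid_n - 1)
  for (k in unique(i)) {
    sp <- seg_speed(curve[[k]], tg)
    cl <- c(0, cumsum((sp[-1] + sp[-grid_n]) / 2 * dt))
    cl <- cl * (seg_len[k] / cl[grid_n])
    idx <- i == k
    rem <- pmin(pmax(s[idx] - cum[k], 0), seg_len[k])
    u[idx] <- (k - 1) + approx(cl, tg, xout = rem, ties = "ordered",
                               rule = 2)$y
  }
  u
}

#' Signed-curvature profile along a composite curve
#'
#' Samples the curve at `n_samples` points uniformly spaced in arc length
#' and records the signed curvature and radius of curvature at each.
#'
#' @param curve A `composite_bezier`.
#' @param n_samples Number of samples (>= 2); default 1024.
#' @return A data frame of class `curvature_profile` with columns `s` (arc
#'   length from the start, px), `u` (global parameter), `kappa` (signed
#'   curvature, 1/px) and `radius` (1/|kappa|, px; `Inf` where |kappa| <
#'   1e-12). Total arc length is attached as attribute `total_length`.
#' @export
curvature_profile <- function(curve, n_samples = 1024) {
  curve <- as_composite(curve)
  if (n_samples < 2) stop("n_samples must be at least 2")
  sl <- seg_lengths(curve)
  total <- sum(sl)
  if (total <= 0) stop("degenerate curve: zero total arc length")
  s <- seq(0, total, length.out = n_samples)
  u <- arclen_to_param(curve, s, sl)
  kappa <- composite_curvature(curve, u)
  radius <- ifelse(abs(kappa) < 1e-12, Inf, 1 / abs(kappa))
  structure(data.frame(s = s, u = u, kappa = kappa, radius = radius),
            total_length = total,
            class = c("curvature_profile", "data.frame"))
}

#' Summarize a curvature profile by its mean absolute radius of curvature
#'
#' Two RC estimators are reported. The primary statistic `rc` is the
#' reciprocal of the mean absolute curvature, 1/mean(|kappa|): it is finite
#' for every non-straight curve even though any S-line passes through an
#' inflection where the pointwise radius diverges. The alternative `alt_rc`
#' is the mean of the finite pointwise radii after discarding the largest
#' `trim` fraction (the samples nearest the inflection).
#'
#' @param profile A `curvature_profile`.
#' @param trim Fraction of the largest radii discarded for `alt_rc`
#'   (default 0.05).
#' @return A list of class `curvature_summary` with elements
#'   `mean_abs_curvature` (1/px), `rc` (px), `alt_rc` (px), `n_samples`.
#' @export
summarize_curvature <- function(profile, trim = 0.05) {
  if (!inherits(profile, "curvature_profile") && !is.data.frame(profile))
    stop("profile must be a curvature_profile")
  if (nrow(profile) == 0) stop("empty curvature profile")
  mac <- mean(abs(profile$kappa))
  rc <- if (mac == 0) Inf else 1 / mac
  finite_r <- sort(profile$radius[is.finite(profile$radius)])
  alt_rc <- if (length(finite_r) == 0) Inf else {
    keep <- seq_len(max(1L, floor(length(finite_r) * (1 - trim))))
    mean(finite_r[keep])
  }
  structure(list(mean_abs_curvature = mac, rc = rc, alt_rc = alt_rc,
                 n_samples = nrow(profile)),
            class = "curvature_summary")
}

#' @export
print.curvature_summary <- function(x, ...) {
  cat(sprintf("Curvature summary over %d samples\n", x$n_samples))
  cat(sprintf("  mean |kappa| : %.6g 1/px\n", x$mean_abs_curvature))
  cat(sprintf("  RC (1/mean|kappa|): %.4g px\n", x$rc))
  cat(sprintf("  alt RC (trimmed mean radius): %.4g px\n", x$alt_rc))
  invisible(x)
}

#' Continuity diagnostics at the joins of a composite curve
#'
#' For each interior join reports the position gap, the absolute angle
#' between the incoming and outgoing tangent directions, and the absolute
#' difference of the signed curvatures evaluated from both sides.
#'
#' @param curve A `composite_bezier`.
#' @return A data frame with one row per join and columns `join`,
#'   `position_gap` (px), `tangent_angle_gap` (radians), `curvature_gap`
#'   (1/px). Empty for single-segment curves.
#' @export
continuity_report <- function(curve) {
  curve <- as_composite(curve)
  n <- length(curve)
  if (n < 2)
    return(data.frame(join = integer(0), position_gap = numeric(0),
                      tangent_angle_gap = numeric(0), curvature_gap = numeric(0)))
  rows <- lapply(seq_len(n - 1L), function(i) {
    a <- curve[[i]]; b <- curve[[i + 1L]]
    pos <- sqrt(sum((a[4, ] - b[1, ])^2))
    ta <- bezier_d1_mat(a, 1)[1, ]
    tb <- bezier_d1_mat(b, 0)[1, ]
    ang <- abs(atan2(ta[1] * tb[2] - ta[2] * tb[1], sum(ta * tb)))
    kg <- abs(bezier_curvature(a, 1) - bezier_curvature(b, 0))
    data.frame(join = i, position_gap = pos, tangent_angle_gap = ang,
               curvature_gap = kg)
  })
  do.call(rbind, rows)
}

#' @export
plot.composite_bezier <- function(x, n = 256, add = FALSE, col = "steelblue",
                                  lwd = 2, ...) {
  u <- seq(0, length(x), length.out = n)
  pts <- composite_eval(x, u)
  if (add) lines(pts, col = col, lwd = lwd, ...)
  else plot(pts, type = "l", asp = 1, col = col, lwd = lwd,
            xlab = "x (px)", ylab = "y (px)", ...)
  invisible(x)
}
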