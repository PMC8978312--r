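# Shared fixtures, built in code.

# Cubic approximation of a quarter circle of radius r (handle factor for
# minimal radial error).
quarter_circle_segment <- function(r = 100) {
  k <- 0.552285
  bezier_segment(c(r, 0), c(r, r * k), c(r * k, r), c(0, r))
}

straight_composite <- function(a = c(0, 0), b = c(3, 3)) {
  d <- b - a
  composite_bezier(bezier_segment(a, a + d / 3, a + 2 * d / 3, b))
}

# Complete balanced toy rating table: n subjects x k lines, entries from a
# deterministic grid unless a matrix is supplied.
toy_ratings <- function(m) {
  n <- nrow(m); k <- ncol(m)
  rating_dataset(data.frame(
    subject = rep(seq_len(n), times = k),
    line = rep(seq_len(k), each = n),
    rating = as.vector(m)))
}

# Central finite-difference signed curvature (independent oracle).
# Fourth-order stencils at a moderate step keep both truncation and
# cancellation error near 1e-10.
fd_curvature <- function(seg, t, h = 3e-3) {
  p <- function(tt) bezier_point(seg, tt)
  d1 <- (p(t - 2 * h) - 8 * p(t - h) + 8 * p(t + h) - p(t + 2 * h)) /
    (12 * h)
  d2 <- (-p(t - 2 * h) + 16 * p(t - h) - 30 * p(t) + 16 * p(t + h) -
           p(t + 2 * h)) / (12 * h^2)
  unname((d1[1] * d2[2] - d1[2] * d2[1]) / sum(d1^2)^1.5)
}

# Random non-degenerate single segment for curvature property tests.
random_segment <- function() {
  repeat {
    cp <- matrix(runif(8, -100, 100), 4, 2)
    s <- try(bezier_segment(cp[1, ], cp[2, ], cp[3, ], cp[4, ]), silent = TRUE)
    if (inherits(s, "try-error")) next
    sp <- try(min(hogarth:::seg_speed(s, seq(0.05, 0.95, length.out = 50))),
              silent = TRUE)
    if (!inherits(sp, "try-error") && sp > 5) return(s)
  }
}

rigid_transform <- function(pts, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(as.matrix(pts) %*% t(R), 2, -shift)
}

transform_curve <- function(curve, angle, shift) {
  composite_bezier(lapply(curve, function(sg) {
    m <- rigid_transform(unclass(sg), angle, shift)
    bezier_segment(m[1, ], m[2, ], m[3, ], m[4, ])
  }))
}
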