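# Least-squares fitting of a composite cubic Bezier to a polyline with
# tangent continuity enforced by construction and curvature equality at
# the joins imposed through a quadratic penalty (continuation to large
# weights), Levenberg-Marquardt inner solver.

as_polyline <- function(points) {
  pts <- as.matrix(points)
  if (is.data.frame(points)) pts <- as.matrix(points[, c("x", "y")])
  if (ncol(pts) != 2 || !is.numeric(pts) || any(!is.finite(pts)))
    stop("a polyline must be a numeric matrix or data frame with columns x, y")
  colnames(pts) <- c("x", "y")
  # drop consecutive duplicates
  if (nrow(pts) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 8) stop("a polyline needs at least 8 distinct points")
  pts
}

# Geometry of the constrained parameterization
# --------------------------------------------
# Free variables for n segments: node positions N_0..N_n, one tangent angle
# per node, and per segment a log handle magnitude at each end. Adjacent
# segments share the node and its tangent direction, so C0 and G1 hold
# exactly by construction; only the curvature equality at joins needs a
# penalty.
#
# Parameter vector layout: [nodes (2(n+1), unless pinned), angles (n+1),
# log-magnitudes (2n: out_0..out_{n-1}, in_1..in_n)]

parse_fit_par <- function(par, n_seg, pinned = NULL) {
  if (is.null(pinned)) {
    nodes <- matrix(par[seq_len(2 * (n_seg + 1))], ncol = 2, byrow = TRUE)
    rest <- par[-seq_len(2 * (n_seg + 1))]
  } else {
    inner <- matrix(par[seq_len(2 * (n_seg - 1))], ncol = 2, byrow = TRUE)
    nodes <- rbind(pinned$first, inner, pinned$last)
    rest <- if (n_seg > 1) par[-seq_len(2 * (n_seg - 1))] else par
  }
  theta <- rest[seq_len(n_seg + 1)]
  mag <- exp(rest[(n_seg + 1) + seq_len(2 * n_seg)])
  list(nodes = nodes, theta = theta,
       out_mag = mag[seq_len(n_seg)], in_mag = mag[n_seg + seq_len(n_seg)])
}

# Signed curvature gaps at joins, computed in closed form from the
# parameter vector: at the end of segment i, kappa = (2/3) w x (A - J +
# o_A u_A) / q^2 with w the join tangent, A/J the segment's nodes, o_A/q
# the handle magnitudes; at the start of segment i+1, kappa = (2/3) w x
# (C - q_C u_C - J) / o^2.
gaps_from_par <- function(par, n_seg, pinned = NULL) {
  if (n_seg < 2) return(numeric(0))
  p <- parse_fit_par(par, n_seg, pinned)
  ct <- cos(p$theta); st <- sin(p$theta)
  vapply(seq_len(n_seg - 1L), function(j) {
    jn <- j + 1L  # node index of the join
    wx <- ct[jn]; wy <- st[jn]
    vinx <- p$nodes[j, 1] + p$out_mag[j] * ct[j] - p$nodes[jn, 1]
    viny <- p$nodes[j, 2] + p$out_mag[j] * st[j] - p$nodes[jn, 2]
    k_in <- (2 / 3) * (wx * viny - wy * vinx) / p$in_mag[j]^2
    voutx <- p$nodes[jn + 1, 1] - p$in_mag[j + 1] * ct[jn + 1] - p$nodes[jn, 1]
    vouty <- p$nodes[jn + 1, 2] - p$in_mag[j + 1] * st[jn + 1] - p$nodes[jn, 2]
    k_out <- (2 / 3) * (wx * vouty - wy * voutx) / p$out_mag[j + 1]^2
    k_in - k_out
  }, numeric(1))
}

fit_params_to_curve <- function(par, n_seg, pinned = NULL) {
  pp <- parse_fit_par(par, n_seg, pinned)
  nodes <- pp$nodes
  theta <- pp$theta
  out_mag <- pp$out_mag
  in_mag <- pp$in_mag
  u <- cbind(cos(theta), sin(theta))
  segs <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    p0 <- nodes[i, ]
    p3 <- nodes[i + 1, ]
    p1 <- p0 + out_mag[i] * u[i, ]
    p2 <- p3 - in_mag[i] * u[i + 1, ]
    segs[[i]] <- structure(rbind(p0 = p0, p1 = p1, p2 = p2, p3 = p3),
                           dimnames = list(c("p0", "p1", "p2", "p3"),
                                           c("x", "y")),
                           class = "bezier_segment")
  }
  structure(segs, class = "composite_bezier")
}

# Curvature gaps at interior joins (signed difference, vector length n-1).
# The speed in the denominator is floored so that a transiently collapsed
# handle during optimization cannot make the objective non-evaluable.
join_curvature_gaps <- function(curve, speed_floor = 1e-9) {
  n <- length(curve)
  if (n < 2) return(numeric(0))
  end_kappa <- function(seg, t) {
    d1 <- bezier_d1_mat(seg, t)[1, ]
    d2 <- bezier_d2_mat(seg, t)[1, ]
    sp <- max(sqrt(sum(d1^2)), speed_floor)
    (d1[1] * d2[2] - d1[2] * d2[1]) / sp^3
  }
  vapply(seq_len(n - 1L), function(i)
    end_kappa(curve[[i]], 1) - end_kappa(curve[[i + 1L]], 0),
    numeric(1))
}

# Vectorized Newton refinement of the perpendicular-foot condition
# f(t) = (B(t) - p) . B'(t) = 0, warm-started from global parameters u.
# Steps may cross segment boundaries (the composite is tangent-continuous
# by construction, so the distance function is smooth enough across
# joins). Fused scalar arithmetic: this sits in the innermost optimizer
# loop. Returns list(u, dist).
refine_projection <- function(curve, pts, u, iters = 8) {
  n_seg <- length(curve)
  m <- nrow(pts)
  px_all <- pts[, 1]; py_all <- pts[, 2]
  cf <- lapply(curve, function(sg) {
    c(sg[1, 1], sg[2, 1], sg[3, 1], sg[4, 1],
      sg[1, 2], sg[2, 2], sg[3, 2], sg[4, 2])
  })
  d2out <- numeric(m)
  for (it in seq_len(iters + 1L)) {
    seg_id <- pmin(floor(u), n_seg - 1) + 1L
    t_all <- u - (seg_id - 1L)
    step <- numeric(m)
    for (i in unique(seg_id)) {
      idx <- which(seg_id == i)
      t <- t_all[idx]
      px <- px_all[idx]; py <- py_all[idx]
      s <- cf[[i]]
      x0 <- s[1]; x1 <- s[2]; x2 <- s[3]; x3 <- s[4]
      y0 <- s[5]; y1 <- s[6]; y2 <- s[7]; y3 <- s[8]
      v <- 1 - t; vv <- v * v; tt <- t * t
      b0 <- vv * v; b1 <- 3 * vv * t; b2 <- 3 * v * tt; b3 <- tt * t
      Bx <- b0 * x0 + b1 * x1 + b2 * x2 + b3 * x3 - px
      By <- b0 * y0 + b1 * y1 + b2 * y2 + b3 * y3 - py
      if (it > iters) {
        d2out[idx] <- Bx * Bx + By * By
        next
      }
      d1x <- 3 * (vv * (x1 - x0) + 2 * v * t * (x2 - x1) + tt * (x3 - x2))
      d1y <- 3 * (vv * (y1 - y0) + 2 * v * t * (y2 - y1) + tt * (y3 - y2))
      d2x <- 6 * (v * (x0 - 2 * x1 + x2) + t * (x1 - 2 * x2 + x3))
      d2y <- 6 * (v * (y0 - 2 * y1 + y2) + t * (y1 - 2 * y2 + y3))
      f <- Bx * d1x + By * d1y
      fp <- d1x * d1x + d1y * d1y + Bx * d2x + By * d2y
      st <- ifelse(abs(fp) > 1e-14, f / fp, 0)
      # cap the step at one segment to keep boundary crossings tame
      step[idx] <- pmin(pmax(st, -1), 1)
    }
    if (it > iters) break
    u <- pmin(pmax(u - step, 0), n_seg)
  }
  list(u = u, dist = sqrt(d2out))
}

# Project points onto a composite curve: per segment, seed from the best
# grid point and Newton-refine; take the minimum over segments (a point
# near a join may have its true foot on either side).
project_points <- function(curve, pts, grid_n = 64) {
  n_seg <- length(curve)
  m <- nrow(pts)
  tg <- seq(0, 1, length.out = grid_n)
  best_d2 <- rep(Inf, m); best_u <- numeric(m)
  refine_cell <- function(seg, j) {
    # bracket of one grid cell each side, fine subgrid, safeguarded Newton
    lo <- tg[pmax(j - 1L, 1L)]
    hi <- tg[pmin(j + 1L, grid_n)]
    t <- tg[j]
    dd <- rowSums((bezier_eval_mat(seg, t) - pts)^2)
    for (ft in seq(0, 1, length.out = 17)) {
      tf <- lo + ft * (hi - lo)
      df <- rowSums((bezier_eval_mat(seg, tf) - pts)^2)
      upd <- df < dd
      t[upd] <- tf[upd]; dd[upd] <- df[upd]
    }
    tn <- t
    for (it in 1:10) {
      b <- bezier_eval_mat(seg, tn); d1 <- bezier_d1_mat(seg, tn)
      d2m <- bezier_d2_mat(seg, tn)
      diffv <- b - pts
      f <- rowSums(diffv * d1)
      fp <- rowSums(d1^2) + rowSums(diffv * d2m)
      step <- ifelse(abs(fp) > 1e-14, f / fp, 0)
      tn <- pmin(pmax(tn - step, lo), hi)
    }
    ddn <- rowSums((bezier_eval_mat(seg, tn) - pts)^2)
    upd <- ddn < dd
    t[upd] <- tn[upd]; dd[upd] <- ddn[upd]
    list(t = t, dd = dd)
  }
  for (i in seq_len(n_seg)) {
    seg <- curve[[i]]
    cp <- bezier_eval_mat(seg, tg)
    d2 <- outer(pts[, 1], cp[, 1], "-")^2 + outer(pts[, 2], cp[, 2], "-")^2
    # refine from up to 3 separated candidate cells per point (the curve
    # may pass near a point on more than one branch)
    for (cand in 1:3) {
      j <- max.col(-d2, ties.method = "first")
      r <- refine_cell(seg, j)
      upd <- r$dd < best_d2
      best_d2[upd] <- r$dd[upd]
      best_u[upd] <- (i - 1) + r$t[upd]
      if (cand == 3) break
      mask <- pmax(j - 3L, 1L)
      for (off in 0:6) {
        col <- pmin(pmax(mask + off, 1L), grid_n)
        d2[cbind(seq_len(m), col)] <- Inf
      }
    }
  }
  list(u = best_u, dist = sqrt(best_d2))
}

#' Minimum distance from a point to a composite Bezier curve
#'
#' Dense per-segment seeding followed by Newton refinement of the
#' perpendicularity condition.
#'
#' @param curve A `composite_bezier`.
#' @param p Numeric length-2 point, or an m x 2 matrix of points.
#' @return Distance(s) in px.
#' @export
point_to_curve_distance <- function(curve, p) {
  curve <- as_composite(curve)
  pts <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  project_points(curve, pts, grid_n = 128)$dist
}

#' Fit a composite cubic Bezier curve to a polyline
#'
#' Minimizes the sum of squared orthogonal distances between the polyline
#' points and the curve, over node positions, shared tangent directions at
#' the nodes, and handle magnitudes. Position (C0) and tangent (G1)
#' continuity at the joins hold exactly by construction; equality of signed
#' curvature across each join is enforced by a quadratic penalty whose
#' weight is increased by continuation, leaving curvature residuals below
#' about 1e-6 per px. Point-to-curve correspondence alternates between
#' Levenberg-Marquardt refits and nearest-point reparameterization; because
#' the join placement makes the problem multimodal, several initial node
#' splits are tried and the best local solution kept.
#'
#' @param polyline An m x 2 matrix or data frame of (x, y) points, m >= 8.
#' @param n_segments Number of cubic segments (>= 1).
#' @param pin_endpoints If `TRUE`, fix the curve endpoints to the first and
#'   last polyline points; by default the endpoints are fitted.
#' @param max_rounds Maximum correspondence/refit rounds per start
#'   (default 10).
#' @param rms_tol Stop a start when the rms deviation improves by less than
#'   this (px; default 1e-6).
#' @param penalty_weights Continuation schedule for the curvature-equality
#'   penalty weight.
#' @return An object of class `bezier_fit` with elements `curve`
#'   (`composite_bezier`), `rms_deviation`, `max_deviation` (px, over all
#'   polyline points, via true nearest-point projection), `n_iterations`
#'   (correspondence rounds used by the winning start), `converged`,
#'   `continuity` (see [continuity_report()]) and the input `polyline`.
#' @export
fit_composite <- function(polyline, n_segments, pin_endpoints = FALSE,
                          max_rounds = 10, rms_tol = 1e-6,
                          penalty_weights = c(1e4, 1e6, 1e8, 1e10)) {
  pts <- as_polyline(polyline)
  n_seg <- as.integer(n_segments)
  if (n_seg < 1) stop("n_segments must be >= 1")
  if (nrow(pts) < 4 * n_seg)
    stop(sprintf("too few points (%d) for %d segments", nrow(pts), n_seg))

  # chord-length parameterization of the data
  chord <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- chord[length(chord)]
  frac <- chord / total
  interp_pt <- function(f) {
    i <- findInterval(f, frac, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(pts) - 1)
    w <- (f - frac[i]) / max(frac[i + 1] - frac[i], 1e-12)
    pts[i, ] + w * (pts[i + 1, ] - pts[i, ])
  }

  pinned <- if (pin_endpoints)
    list(first = pts[1, ], last = pts[nrow(pts), ]) else NULL
  bbox_diag <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))

  # Orthogonal-distance residuals: the foot points are re-found by a few
  # Newton steps warm-started from the current correspondence, so the
  # solver sees the sliding-invariant geometric distance.
  m <- nrow(pts)
  resid_fun <- function(par, tvec, w) {
    curve <- fit_params_to_curve(par, n_seg, pinned)
    ref <- refine_projection(curve, pts, tvec, iters = 4)
    u <- ref$u
    # anchor the extreme polyline points to the curve ends: without this,
    # a free-endpoint orthogonal-distance fit can grow a spurious tail
    # beyond the data at no cost
    u[1] <- 0
    u[m] <- n_seg
    hat <- composite_eval(curve, u)
    r <- as.vector(pts - hat)
    out <- c(r, sqrt(w) * gaps_from_par(par, n_seg, pinned))
    out[!is.finite(out)] <- 1e6
    out
  }

  fit_once <- function(inner_fracs) {
    node_s <- c(0, inner_fracs, 1)
    nodes0 <- t(vapply(node_s, interp_pt, numeric(2)))
    theta0 <- vapply(seq_len(n_seg + 1), function(j) {
      f <- node_s[j]
      a <- interp_pt(max(f - 0.1 / n_seg, 0))
      b <- interp_pt(min(f + 0.1 / n_seg, 1))
      atan2(b[2] - a[2], b[1] - a[1])
    }, numeric(1))
    seg_chord <- sqrt(rowSums(diff(nodes0)^2))
    logmag0 <- log(rep(pmax(seg_chord / 3, 1e-6), 2))
    par <- c(if (is.null(pinned)) as.vector(t(nodes0))
             else if (n_seg > 1) as.vector(t(nodes0[2:n_seg, , drop = FALSE]))
             else numeric(0),
             theta0, logmag0)
    # correspondence from the chord fractions and the initial node split
    tvec <- pmin(findInterval(frac, node_s, rightmost.closed = TRUE) - 1 +
                 sapply(frac, function(f) {
                   i <- findInterval(f, node_s, rightmost.closed = TRUE)
                   i <- min(max(i, 1), n_seg)
                   (f - node_s[i]) / max(node_s[i + 1] - node_s[i], 1e-12)
                 }), n_seg)

    # box constraints keep the solver away from collapsed/runaway handles
    n_node_par <- if (is.null(pinned)) 2 * (n_seg + 1) else 2 * (n_seg - 1)
    lower <- c(rep(min(pts) - bbox_diag, n_node_par),
               theta0 - pi, rep(log(bbox_diag * 1e-4), 2 * n_seg))
    upper <- c(rep(max(pts) + bbox_diag, n_node_par),
               theta0 + pi, rep(log(bbox_diag * 2), 2 * n_seg))

    run_lm <- function(par, tvec, w, maxiter = 100) {
      minpack.lm::nls.lm(
        par, lower = lower, upper = upper, fn = resid_fun,
        tvec = tvec, w = w,
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ftol = 1e-13, ptol = 1e-13,
                                             maxfev = 10000))
    }
    # phase 1: converge the geometry under the mildest penalty weight
    rms <- Inf; converged <- FALSE; rounds <- 0
    for (round in seq_len(max_rounds)) {
      rounds <- round
      lm <- run_lm(par, tvec, penalty_weights[1])
      par <- lm$par
      curve <- fit_params_to_curve(par, n_seg, pinned)
      proj <- project_points(curve, pts)
      tvec <- proj$u
      new_rms <- sqrt(mean(proj$dist^2))
      if (rms - new_rms < rms_tol) {
        rms <- min(rms, new_rms)
        converged <- TRUE
        break
      }
      rms <- new_rms
    }
    # phase 2: continuation to the stiffer penalty weights
    for (w in penalty_weights[-1]) {
      lm <- run_lm(par, tvec, w)
      par <- lm$par
      curve <- fit_params_to_curve(par, n_seg, pinned)
      tvec <- project_points(curve, pts)$u
    }
    curve <- fit_params_to_curve(par, n_seg, pinned)
    proj <- project_points(curve, pts)
    list(curve = curve, rms = sqrt(mean(proj$dist^2)),
         max = max(proj$dist), rounds = rounds, converged = converged)
  }

  # multistart over initial join splits (the objective is multimodal in
  # the join placement); stop early once a start clearly succeeds
  eq <- seq_len(n_seg - 1) / n_seg
  starts <- unique(lapply(
    list(0, -0.12, 0.12, -0.24, 0.24),
    function(sh) pmin(pmax(eq + sh, 0.05), 0.95)))
  best <- NULL
  all_rms <- numeric(0)
  for (st in starts) {
    cand <- suppressWarnings(fit_once(st))
    all_rms <- c(all_rms, cand$rms)
    if (is.null(best) || cand$rms < best$rms) best <- cand
    if (best$rms <= 1e-7 * bbox_diag) break
    # consensus stop: after three starts, two landing on the same optimum
    srt <- sort(all_rms)
    if (length(srt) >= 3 && srt[2] <= 1.05 * srt[1]) break
  }

  structure(list(curve = best$curve,
                 rms_deviation = best$rms,
                 max_deviation = best$max,
                 n_iterations = best$rounds,
                 converged = best$converged,
                 continuity = continuity_report(best$curve),
                 polyline = pts),
            class = "bezier_fit")
}

#' @export
print.bezier_fit <- function(x, ...) {
  cat(sprintf("Composite Bezier fit: %d segment(s), %d polyline points\n",
              length(x$curve), nrow(x$polyline)))
  cat(sprintf("  rms deviation %.4g px, max %.4g px (%s after %d round(s))\n",
              x$rms_deviation, x$max_deviation,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  if (nrow(x$continuity) > 0)
    cat(sprintf("  worst join: tangent gap %.2g rad, curvature gap %.2g 1/px\n",
                max(x$continuity$tangent_angle_gap),
                max(x$continuity$curvature_gap)))
  invisible(x)
}

#' @export
residuals.bezier_fit <- function(object, ...) {
  point_to_curve_distance(object$curve, object$polyline)
}

#' @export
plot.bezier_fit <- function(x, ...) {
  plot(x$polyline, pch = 16, cex = 0.4, col = "grey40", asp = 1,
       xlab = "x (px)", ylab = "y (px)", ...)
  plot(x$curve, add = TRUE)
  invisible(x)
}

#' Choose the number of Bezier segments for a polyline
#'
#' Returns the smallest segment count (up to `max_segments`) whose fit
#' achieves an rms deviation at most `rel_tol` times the diagonal of the
#' polyline's bounding box. If none does, returns `max_segments` with
#' attribute `tolerance_met = FALSE` and a warning.
#'
#' @param polyline An m x 2 matrix or data frame of (x, y) points.
#' @param max_segments Largest segment count to try (default 4).
#' @param rel_tol rms tolerance as a fraction of the bounding-box diagonal
#'   (default 0.005).
#' @param ... Passed to [fit_composite()].
#' @return Integer segment count, with attributes `rms_deviation` and
#'   `tolerance_met`.
#' @export
select_segment_count <- function(polyline, max_segments = 4, rel_tol = 0.005,
                                 ...) {
  pts <- as_polyline(polyline)
  if (max_segments < 1) stop("max_segments must be >= 1")
  diag <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  tol <- rel_tol * diag
  last_rms <- NA_real_
  for (n in seq_len(max_segments)) {
    if (nrow(pts) < 4 * n) break
    fit <- fit_composite(pts, n, ...)
    last_rms <- fit$rms_deviation
    if (fit$rms_deviation <= tol)
      return(structure(n, rms_deviation = fit$rms_deviation,
                       tolerance_met = TRUE))
  }
  warning(sprintf("no fit with <= %d segments reached rms tolerance %.3g px",
                  max_segments, tol))
  structure(max_segments, rms_deviation = last_rms, tolerance_met = FALSE)
}
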