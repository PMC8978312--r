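# Synthetic stimuli and behavioural data: S-shaped line families calibrated
# to target RC values, digitized noisy polylines, and seeded simulators for
# rating and forced-choice experiments under the quadratic curvature-beauty
# model.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# Point-symmetric two-segment S-curve between (0, 0) and (0, height).
# Each half is a cubic whose two interior control points coincide at
# X = (-(h/4) tan(bulge), h/4) (lower half), which makes the signed
# curvature vanish at both ends of the half: the curve is straight at its
# endpoints, bends most strongly mid-arc, and passes through its central
# inflection with curvature zero from both sides (exact G2 join by the
# point symmetry). `bulge` is the tangent tilt away from the vertical
# chord at the endpoints and the midpoint: 0 gives a straight line,
# values near pi/2 a strongly bulging S.
s_curve <- function(bulge, height = 100) {
  if (bulge <= 0 || bulge >= pi / 2) stop("bulge must lie in (0, pi/2)")
  m <- c(0, height / 2)
  x <- c(-(height / 4) * tan(bulge), height / 4)
  lower <- bezier_segment(c(0, 0), x, x, m)
  upper <- bezier_segment(m, 2 * m - x, 2 * m - x, c(0, height))
  composite_bezier(lower, upper)
}

rc_of_bulge <- function(bulge, height, n_samples = 1024) {
  summarize_curvature(curvature_profile(s_curve(bulge, height),
                                        n_samples))$rc
}

#' Generate a family of S-shaped lines with target RC values
#'
#' Builds point-symmetric two-segment composite Bezier S-curves sharing the
#' same endpoints and height, whose bulge parameter (the tangent tilt at
#' the central inflection) is calibrated by root-finding so that each
#' line's mean absolute radius of curvature matches its target within the
#' requested tolerance. The default targets are the RC values of the seven
#' classic waving lines, 108, 109, 98, 66, 59, 48 and 48 px.
#'
#' @param target_rcs Target RC values in px (positive).
#' @param height Common line height in px (default 100).
#' @param tol Relative calibration tolerance (default 0.005).
#' @return A list of `composite_bezier` curves, with the achieved bulge
#'   parameters attached as attribute `bulge` and achieved RCs as `rc`.
#' @export
make_line_family <- function(target_rcs = c(108, 109, 98, 66, 59, 48, 48),
                             height = 100, tol = 0.005) {
  if (any(!is.finite(target_rcs)) || any(target_rcs <= 0))
    stop("target RC values must be positive and finite")
  # the bulge-RC relation is U-shaped; calibration uses the gentle,
  # monotone-decreasing branch
  lo <- 1e-3; hi <- 0.9
  rc_hi <- rc_of_bulge(hi, height)
  rc_lo <- rc_of_bulge(lo, height)
  bulges <- vapply(seq_along(target_rcs), function(i) {
    tgt <- target_rcs[i]
    if (tgt > rc_lo || tgt < rc_hi)
      stop(sprintf("line %d: target RC %.3g px outside attainable range [%.3g, %.3g]",
                   i, tgt, rc_hi, rc_lo))
    uniroot(function(b) rc_of_bulge(b, height) - tgt,
            c(lo, hi), tol = 1e-8)$root
  }, numeric(1))
  curves <- lapply(bulges, s_curve, height = height)
  achieved <- vapply(curves, function(cv)
    summarize_curvature(curvature_profile(cv, 1024))$rc, numeric(1))
  err <- abs(achieved - target_rcs) / target_rcs
  if (any(err > tol))
    stop(sprintf("calibration failed for line %d (relative error %.3g)",
                 which.max(err), max(err)))
  structure(curves, bulge = bulges, rc = achieved)
}

#' Digitize a curve into a noisy polyline
#'
#' Samples the curve at `n_points` positions uniformly spaced in arc length
#' and adds isotropic Gaussian jitter, emulating the pixel-level
#' digitization of a drawn line.
#'
#' @param curve A `composite_bezier`.
#' @param n_points Number of samples (>= 8; default 200).
#' @param jitter_sd Standard deviation of the jitter per coordinate, px
#'   (default 0).
#' @param seed Integer seed; identical seeds give identical polylines.
#' @return An `n_points` x 2 matrix with columns `x`, `y`.
#' @export
digitize <- function(curve, n_points = 200, jitter_sd = 0, seed = NULL) {
  curve <- as_composite(curve)
  if (n_points < 8) stop("n_points must be at least 8")
  sl <- seg_lengths(curve)
  s <- seq(0, sum(sl), length.out = n_points)
  u <- arclen_to_param(curve, s, sl)
  pts <- composite_eval(curve, u)
  if (jitter_sd > 0)
    pts <- pts + with_seed(seed,
      matrix(rnorm(2 * n_points, sd = jitter_sd), ncol = 2))
  colnames(pts) <- c("x", "y")
  pts
}

#' Configuration for a simulated rating/choice experiment
#'
#' @param a0,a1,a2 Coefficients of the quadratic curvature-beauty model
#'   (rating units; per px; per px^2).
#' @param rcs RC values of the lines shown, px.
#' @param n_subjects Number of subjects (>= 2; default 70).
#' @param subject_sd SD of the per-subject additive intercept, rating units
#'   (default 10).
#' @param noise_sd SD of the per-trial residual, rating units (default 15).
#' @param choice_concentration Softmax concentration of the choice rule in
#'   1/rating-unit; 0 gives uniform random choices, large values the
#'   subject's own maximum-rated line (default 0.2).
#' @param seed Integer seed (default 1753).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(a0 = -109, a1 = 4.98, a2 = -0.033,
                              rcs = c(108, 109, 98, 66, 59, 48, 48),
                              n_subjects = 70, subject_sd = 10,
                              noise_sd = 15, choice_concentration = 0.2,
                              seed = 1753) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (subject_sd < 0 || noise_sd < 0) stop("sds must be nonnegative")
  if (any(rcs <= 0)) stop("rcs must be positive")
  structure(list(a0 = unname(a0), a1 = unname(a1), a2 = unname(a2),
                 rcs = unname(rcs),
                 n_subjects = as.integer(n_subjects),
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 choice_concentration = choice_concentration,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Population mean ratings implied by a configuration
#'
#' @param config An `experiment_config`.
#' @return Per-line noise-free model means, before clipping to [1, 100].
#' @export
model_means <- function(config) {
  config$a0 + config$a1 * config$rcs + config$a2 * config$rcs^2
}

#' Simulate a rating experiment
#'
#' Each subject j rates each line i once:
#' rating_ij = clip(a0 + a1 rc_i + a2 rc_i^2 + s_j + e_ij, 1, 100) with
#' s_j ~ N(0, subject_sd) a subject intercept and e_ij ~ N(0, noise_sd) a
#' trial residual.
#'
#' @param config An `experiment_config`.
#' @return A `rating_dataset` (without choices). The fraction of clipped
#'   ratings is attached as attribute `clip_rate`.
#' @export
simulate_ratings <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  k <- length(config$rcs)
  n <- config$n_subjects
  mu <- model_means(config)
  raw <- with_seed(config$seed, {
    s_j <- rnorm(n, sd = config$subject_sd)
    e <- matrix(rnorm(n * k, sd = config$noise_sd), n, k)
    outer(s_j, mu, "+") + e
  })
  clipped <- pmin(pmax(raw, 1), 100)
  out <- rating_dataset(data.frame(
    subject = rep(seq_len(n), times = k),
    line = rep(seq_len(k), each = n),
    rating = as.vector(clipped)))
  attr(out, "clip_rate") <- mean(raw != clipped)
  out
}

#' Simulate a forced-choice task from rated lines
#'
#' Each subject chooses line i with probability proportional to
#' exp(concentration x their own rating of line i).
#'
#' @param config An `experiment_config` (provides the concentration and
#'   seed; the choice seed is offset from the rating seed so the two tasks
#'   use independent streams).
#' @param data A `rating_dataset` with complete ratings.
#' @return The dataset with a `choices` component filled in.
#' @export
simulate_choices <- function(config, data) {
  stopifnot(inherits(config, "experiment_config"))
  m <- rating_matrix(data)
  lines <- as.numeric(colnames(m))
  conc <- config$choice_concentration
  choices <- with_seed(config$seed + 104729L, {
    apply(m, 1, function(r) {
      if (is.infinite(conc)) return(lines[which.max(r)])
      w <- exp(conc * (r - max(r)))
      sample(lines, 1, prob = w / sum(w))
    })
  })
  data$choices <- data.frame(subject = rownames(m), choice = unname(choices))
  data
}

#' Random smooth two-segment composite curve
#'
#' Draws a random composite cubic Bezier with exact tangent continuity and
#' exact curvature equality at the join (the outgoing handle magnitude is
#' solved in closed form), useful as ground truth in fitting studies.
#'
#' @param seed Integer seed.
#' @param scale Overall size in px (default 100).
#' @return A `composite_bezier` with two segments, C2-smooth at the join.
#' @export
random_smooth_composite <- function(seed = NULL, scale = 100) {
  with_seed(seed, {
    repeat {
      nodes <- matrix(runif(6, -1, 1), 3, 2) * scale
      nodes[2, ] <- (nodes[1, ] + nodes[3, ]) / 2 + runif(2, -0.2, 0.2) * scale
      theta <- runif(3, -pi, pi)
      u <- cbind(cos(theta), sin(theta))
      o0 <- runif(1, 0.2, 0.5) * scale
      q1 <- runif(1, 0.2, 0.5) * scale
      q2 <- runif(1, 0.2, 0.5) * scale
      cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]
      # curvature into the join is -(2/3) d / q1^2; out of it, (2/3) cc / o1^2
      d <- cross2(u[2, ], nodes[2, ] - nodes[1, ] - o0 * u[1, ])
      cc <- cross2(u[2, ], nodes[3, ] - q2 * u[3, ] - nodes[2, ])
      if (sign(d) == sign(cc) || abs(d) < 1e-3 || abs(cc) < 1e-3) next
      o1 <- q1 * sqrt(-cc / d)  # matches curvature across the join exactly
      if (o1 < 0.15 * scale || o1 > 0.6 * scale) next
      seg1 <- bezier_segment(nodes[1, ], nodes[1, ] + o0 * u[1, ],
                             nodes[2, ] - q1 * u[2, ], nodes[2, ])
      seg2 <- bezier_segment(nodes[2, ], nodes[2, ] + o1 * u[2, ],
                             nodes[3, ] - q2 * u[3, ], nodes[3, ])
      curve <- composite_bezier(seg1, seg2)
      # reject near-cusps and kinks: identifiable ground truth only
      tg <- seq(0, 1, length.out = 101)
      speeds <- unlist(lapply(curve, seg_speed, t = tg))
      kappas <- unlist(lapply(curve, bezier_curvature, t = tg))
      rep <- continuity_report(curve)
      if (max(rep$curvature_gap) < 1e-9 && arc_length(curve) > scale &&
          min(speeds) > 0.3 * scale && max(abs(kappas)) < 10 / scale)
        return(curve)
    }
  })
}
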