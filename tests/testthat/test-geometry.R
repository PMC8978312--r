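test_that("segment evaluation interpolates endpoints and the de Casteljau midpoint", {
  seg <- bezier_segment(c(0, 0), c(1, 0), c(2, 1), c(3, 1))
  expect_equal(unname(bezier_point(seg, 0)), c(0, 0))
  expect_equal(unname(bezier_point(seg, 1)), c(3, 1))
  expect_equal(unname(bezier_point(seg, 0.5)), c(1.5, 0.5))
  expect_error(bezier_point(seg, 1.2), "\\[0, 1\\]")
  # a fully degenerate quadruple is rejected by the constructor, but the
  # raw evaluator still returns the constant point
  expect_error(bezier_segment(c(2, 2), c(2, 2), c(2, 2), c(2, 2)),
               "degenerate")
  const <- structure(matrix(2, 4, 2), class = "bezier_segment")
  expect_equal(unname(hogarth:::bezier_eval_mat(const, 0.3)[1, ]), c(2, 2))
})

test_that("signed curvature matches the closed form and sign convention", {
  line <- bezier_segment(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  expect_equal(bezier_curvature(line, c(0, 0.3, 0.9)), c(0, 0, 0))
  seg <- bezier_segment(c(0, 0), c(1, 0), c(2, 1), c(3, 1))
  expect_equal(bezier_curvature(seg, 0), 18 / 27, tolerance = 1e-12)
  # counterclockwise quarter circle: positive curvature ~ 1/r
  qc <- quarter_circle_segment(100)
  k <- bezier_curvature(qc, seq(0, 1, length.out = 101))
  expect_true(all(k > 0))
  expect_true(all(abs(k - 0.01) / 0.01 < 0.03))
  degen <- structure(rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 2)),
                     class = "bezier_segment")
  expect_error(bezier_curvature(degen, 0), "degenerate tangent")
})

test_that("analytic curvature agrees with central finite differences", {
  set.seed(11)
  for (i in 1:100) {
    seg <- random_segment()
    for (t in runif(10, 0.05, 0.95)) {
      expect_equal(bezier_curvature(seg, t), fd_curvature(seg, t),
                   tolerance = 1e-6)
    }
  }
})

test_that("curvature transforms correctly under similarity and rigid motion", {
  set.seed(21)
  ts <- seq(0.05, 0.95, length.out = 7)
  for (i in 1:20) {
    seg <- random_segment()
    k <- bezier_curvature(seg, ts)
    s <- runif(1, 0.2, 5)
    scaled <- bezier_segment(s * seg[1, ], s * seg[2, ], s * seg[3, ],
                             s * seg[4, ])
    expect_equal(bezier_curvature(scaled, ts), k / s, tolerance = 1e-10)
    moved <- transform_curve(composite_bezier(seg), runif(1, -pi, pi),
                             runif(2, -50, 50))[[1]]
    expect_equal(bezier_curvature(moved, ts), k, tolerance = 1e-10)
    flipped <- bezier_segment(seg[1, ] * c(1, -1), seg[2, ] * c(1, -1),
                              seg[3, ] * c(1, -1), seg[4, ] * c(1, -1))
    expect_equal(bezier_curvature(flipped, ts), -k, tolerance = 1e-10)
  }
})

test_that("arc length is additive, exceeds the chord, and matches pi*r/2", {
  st <- straight_composite(c(0, 0), c(3, 3))
  expect_equal(arc_length(st), 3 * sqrt(2), tolerance = 1e-10)
  qc <- composite_bezier(quarter_circle_segment(100))
  expect_equal(arc_length(qc), pi * 100 / 2, tolerance = 1e-3 * 157)
  seg <- bezier_segment(c(0, 0), c(10, 0), c(20, 10), c(30, 10))
  seg2 <- bezier_segment(c(30, 10), c(40, 10), c(50, 20), c(60, 20))
  two <- composite_bezier(seg, seg2)
  expect_equal(arc_length(two), 2 * arc_length(composite_bezier(seg)),
               tolerance = 1e-9)
  expect_equal(arc_length(two, up_to = 1),
               arc_length(composite_bezier(seg)), tolerance = 1e-9)
  set.seed(5)
  for (i in 1:10) {
    cv <- random_smooth_composite(seed = i)
    ends <- rbind(bezier_point(cv[[1]], 0), bezier_point(cv[[2]], 1))
    expect_gte(arc_length(cv), sqrt(sum((ends[1, ] - ends[2, ])^2)))
  }
})

test_that("curvature profiles are uniform in arc length with correct radii", {
  cv <- random_smooth_composite(seed = 4)
  pr <- curvature_profile(cv, 1024)
  expect_equal(nrow(pr), 1024)
  expect_equal(pr$s[1], 0)
  total <- arc_length(cv)
  expect_equal(pr$s[1024], total, tolerance = 1e-3 * total)
  gaps <- diff(pr$s)
  expect_true(all(abs(gaps - mean(gaps)) < 1e-3 * total))
  # points at the sampled parameters really are where s says they are
  expect_true(all(abs(pr$radius - 1 / abs(pr$kappa)) < 1e-9 |
                    is.infinite(pr$radius)))
  st <- straight_composite()
  prs <- curvature_profile(st, 64)
  expect_true(all(prs$kappa == 0))
  expect_true(all(is.infinite(prs$radius)))
  # an S-line crosses zero curvature exactly once
  s <- hogarth:::s_curve(0.5)
  k <- curvature_profile(s, 512)$kappa
  expect_equal(sum(diff(sign(k[k != 0])) != 0), 1)
  expect_error(curvature_profile(cv, 1), "at least 2")
})

test_that("curvature summaries give both RC estimators", {
  qc <- composite_bezier(quarter_circle_segment(50))
  sm <- summarize_curvature(curvature_profile(qc, 512))
  expect_equal(sm$rc, 50, tolerance = 0.03 * 50)
  expect_equal(sm$alt_rc, 50, tolerance = 0.03 * 50)
  # half the samples at |k| = 1/40, half at 1/80
  pr <- structure(data.frame(s = seq(0, 1, length.out = 100),
                             u = seq(0, 1, length.out = 100),
                             kappa = rep(c(1 / 40, -1 / 80), each = 50),
                             radius = rep(c(40, 80), each = 50)),
                  class = c("curvature_profile", "data.frame"))
  sm2 <- summarize_curvature(pr)
  expect_equal(sm2$mean_abs_curvature, 0.01875, tolerance = 1e-12)
  expect_equal(sm2$rc, 160 / 3, tolerance = 1e-9)
  st <- summarize_curvature(curvature_profile(straight_composite(), 64))
  expect_identical(st$rc, Inf)
  expect_equal(st$mean_abs_curvature, 0)
})

test_that("continuity reports flag corners and pass smooth joins", {
  single <- straight_composite()
  expect_equal(nrow(continuity_report(single)), 0)
  cv <- random_smooth_composite(seed = 7)
  rep <- continuity_report(cv)
  expect_lt(rep$tangent_angle_gap, 1e-9)
  expect_lt(rep$curvature_gap, 1e-9)
  expect_equal(rep$position_gap, 0)
  # mirrored handles give G1 by construction even with a curvature jump
  a <- bezier_segment(c(0, 0), c(10, 0), c(20, 5), c(30, 5))
  b <- bezier_segment(c(30, 5), c(40, 5), c(70, 40), c(80, 40))
  g1 <- continuity_report(composite_bezier(a, b))
  expect_lt(g1$tangent_angle_gap, 1e-9)
  corner <- bezier_segment(c(30, 5), c(30, 15), c(30, 30), c(30, 45))
  g0 <- continuity_report(composite_bezier(a, corner))
  expect_gt(g0$tangent_angle_gap, 0.1)
})

test_that("composite constructor enforces shared endpoints", {
  a <- bezier_segment(c(0, 0), c(1, 0), c(2, 1), c(3, 1))
  b <- bezier_segment(c(3.1, 1), c(4, 1), c(5, 2), c(6, 2))
  expect_error(composite_bezier(a, b), "share an endpoint")
})
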