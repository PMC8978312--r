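Package: hogarth
Title: Curvature Analysis and Preference Modelling for Hogarth's Waving Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative study of S-shaped ("waving") lines in
    empirical aesthetics. Fits composite cubic Bezier curves to digitized
    polylines under tangent- and curvature-continuity constraints at the
    joins, computes signed-curvature and radius-of-curvature profiles along
    the fitted curves, summarizes each line by its mean absolute radius of
    curvature (RC), and models mean beauty ratings as a concave quadratic
    function of RC. Includes the behavioural statistics used with such
    rating and forced-choice experiments (one-way repeated-measures ANOVA
    with Greenhouse-Geisser correction and generalized eta squared,
    Bonferroni-adjusted paired comparisons, choice/maximum-rating
    correlation) and seeded simulators for line families calibrated to
    target RC values, digitized noisy polylines, and rating/choice data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
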