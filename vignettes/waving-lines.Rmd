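---
title: "Curvature and the beauty of waving lines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature and the beauty of waving lines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(hogarth)
```

## The scientific problem

William Hogarth's *The Analysis of Beauty* (1753) shows a scale of seven
S-shaped "waving" lines, of which he declared the fourth — neither too
straight nor bulging too much — the *line of beauty*. Modern empirical
aesthetics asks whether this preference is real and, if so, what objective
property of the lines drives it. The leading candidate is curvature: each
line can be summarized by a single number, the mean absolute radius of
curvature (RC, in pixels), and mean beauty ratings can then be modelled as
a function of RC. The hypothesis of an optimum at intermediate curvature
is an inverted-U (concave quadratic) relation,

$$B = a_0 + a_1\,\mathrm{RC} + a_2\,\mathrm{RC}^2,\qquad a_2 < 0 ,$$

whose vertex $-a_1/(2 a_2)$ is the most-preferred radius of curvature.

This package provides the full chain of tools such a study needs:

1. **geometry** — cubic Bézier segments and composite curves, signed
   curvature, arc length, curvature profiles and RC summaries;
2. **fitting** — least-squares fitting of a composite cubic Bézier to a
   digitized polyline under tangent- and curvature-continuity constraints
   at the joins, plus segment-count selection;
3. **the beauty model** — the quadratic regression above, with classed
   fits (`beauty_fit`) and the usual methods;
4. **behavioural statistics** — choice tallies, per-line means,
   repeated-measures ANOVA with Greenhouse–Geisser correction and
   generalized eta squared, Bonferroni-adjusted paired comparisons, and
   the correlation between a subject's forced choice and their own
   maximum-rated line;
5. **simulators** — seeded generators for S-line families calibrated to
   target RC values, noisy digitizations, and full rating/choice
   experiments.

No raw behavioural data or engraving scans ship with the package; the
simulators stand in for both, and every parameter below is stated with its
default and rationale.

## Curves and curvature

A cubic Bézier segment is determined by four control points; composites
chain segments so that the last control point of one is the first of the
next. Signed curvature is computed analytically,
$\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$, positive where the curve
turns counterclockwise when traversed bottom-to-top in y-up coordinates
(so the convex upper arc of an S has $\kappa > 0$; image-derived
coordinates should be imported with `y_flip = TRUE`).

Arc length uses 24-point Gauss–Legendre quadrature per segment. Inverting
arc length (needed for uniform-arc-length sampling) uses a per-segment
cumulative-trapezoid table of the speed on 1025 nodes, rescaled so segment
boundaries are exact and inverted by monotone interpolation; the sampling
positions are accurate to far better than the 0.1 %-of-length contract of
`curvature_profile()`.

### The RC statistic

"Mean absolute radius of curvature" is ambiguous: every S-line passes
through an inflection where the pointwise radius $1/|\kappa|$ diverges, so
the naive mean of radii is infinite. `summarize_curvature()` therefore
reports two estimators:

* `rc` (primary): $1/\operatorname{mean}(|\kappa|)$ over 1024
  uniform-arc-length samples — finite for every non-straight curve and
  monotone in overall bend;
* `alt_rc`: the mean of the finite pointwise radii after discarding the
  largest 5 % (the samples nearest the inflection).

Both are reported; neither is claimed to be the historically used
estimator. All calibration in this package uses `rc`. Note that the
sample mean of $|\kappa|$ converges only at rate $1/n$ in the sample
count when curvature is concentrated near the profile's ends, which is
why the same `n_samples` (default 1024) should be used when comparing RC
values.

## Fitting composite curves to polylines

`fit_composite()` fits an $n$-segment composite cubic Bézier to an ordered
polyline. The parameterization makes position and tangent continuity hold
exactly by construction: the free variables are the node positions, one
tangent angle per node shared by the adjacent segments, and a log handle
magnitude per segment end. Equality of signed curvature across each join
is imposed by a quadratic penalty whose weight is raised by continuation
(10^4 → 10^6 → 10^8 → 10^10) once the geometry has converged; converged
fits show join curvature gaps below 10^-8 px^-1, and the tangent gap is
zero by construction.

Numerical design choices that proved load-bearing:

* **Orthogonal-distance residuals.** The residual for each polyline point
  is its offset from the nearest curve point, re-found inside every
  objective evaluation by a few Newton steps warm-started from the current
  correspondence (steps may cross segment joins, which are
  tangent-continuous). A fixed-correspondence alternation — refit, then
  re-project — converges an order of magnitude more slowly because it
  penalizes tangential sliding.
* **Multistart.** The join placement makes the objective multimodal. Five
  initial node splits (equal arc-length fractions shifted by 0, ±0.12,
  ±0.24) are tried; a start that reaches machine-precision residuals ends
  the search immediately, and otherwise the search stops once three starts
  have run and the two best agree within 5 %.
* **End anchoring.** The first and last polyline points are assigned to
  the curve ends inside the residual. Endpoints remain free parameters,
  but without this assignment an orthogonal-distance fit can grow a
  spurious straight tail beyond the data at zero cost — invisible in the
  residual, catastrophic for curvature summaries.
* **Bounds.** Node positions are boxed to the data's bounding box padded
  by one diagonal, tangent angles to ±π around their chord estimates, and
  log handle magnitudes to [10^-4, 2] × the bounding-box diagonal, which
  keeps the solver away from collapsed or runaway handles.

On noiseless samples of smooth two-segment composites the fit recovers the
generating curve to ~10^-14 px rms; with 0.5 px Gaussian jitter on 200
points the rms deviation stays at the noise level (≤ 1 px).

`select_segment_count()` returns the smallest segment count whose fit
reaches an rms deviation of `rel_tol` (default 0.005) times the
bounding-box diagonal — a threshold at which one-segment, two-segment and
multi-lobe fixtures separate cleanly.

## The synthetic line family

`make_line_family()` builds point-symmetric two-segment S-curves between
(0, 0) and (0, `height`) whose RC is calibrated to given targets (defaults:
108, 109, 98, 66, 59, 48, 48 px — the classic seven-line scale). Each half
is a cubic whose two interior control points coincide at
$X = (\mp(h/4)\tan\beta,\ h/4)$, where $\beta$ is the *bulge* (the tangent
tilt away from the vertical chord). This construction has three useful
exact properties: curvature vanishes at both endpoints, curvature vanishes
at the central inflection from both sides (so the join is G2 by the point
symmetry), and the curve has exactly one inflection. Because the
endpoints are the hardest region to fit from noisy data, a family whose
curvature is concentrated mid-arc makes the RC statistic robust to
digitization noise; an earlier collinear-handle construction concentrated
curvature at the endpoints and was abandoned for exactly this reason.

The bulge→RC map is U-shaped with a minimum near 0.39 × height; the
calibration root-finds on the gentle, monotone-decreasing branch
(bulge ≤ 0.9 rad). The default `height` of 100 px puts all seven printed
targets comfortably inside the attainable range while keeping the stimuli
at a realistic scan scale. Calibration is by `uniroot` against the
package's own RC computation, to 0.5 % by default.

`digitize()` samples a curve at `n_points` uniform-arc-length positions
and adds isotropic Gaussian jitter (seeded). For end-to-end RC recovery
(digitize at 0.25 px jitter → fit → summarize) the package uses 1600
points per line: the RC error then stays within ~2 % across seeds,
whereas 200-point digitizations leave RC of the gentlest lines with
errors up to ~20 % — RC is a mean of small curvatures and inherits all
of the fit's curvature noise.

## The rating and choice experiment model

`simulate_ratings()` draws, for subject $j$ and line $i$,

$$\mathrm{rating}_{ij} = \mathrm{clip}\big(a_0 + a_1\,\mathrm{RC}_i +
a_2\,\mathrm{RC}_i^2 + s_j + e_{ij},\ 1,\ 100\big),$$

with a Gaussian subject intercept $s_j \sim N(0, \sigma_s^2)$ and
residual $e_{ij} \sim N(0, \sigma_e^2)$. This noise model is the
package's own invention — published work reports only summary
statistics — with defaults $\sigma_s = 10$, $\sigma_e = 15$ chosen to
give per-line standard errors of the magnitude seen in published rating
plots, and 70 subjects by default. The visual-analog scale is clipped to
[1, 100]; at the default coefficients no noise-free line mean comes near
the bounds, and the achieved clipping fraction is attached to every
simulated dataset as `attr(, "clip_rate")`. Note that clipping biases
line means slightly (~1 rating unit at the default noise), which matters
when testing exact coefficient recovery — use moderate noise for that.

`simulate_choices()` implements a softmax choice rule: subject $j$ picks
line $i$ with probability $\propto \exp(c \cdot \mathrm{rating}_{ij})$.
The concentration $c$ (default 0.2 per rating unit) spans uniform choice
($c = 0$) to deterministic choice of the subject's own maximum
($c \to \infty$). The choice stream is seeded independently of the rating
stream (offset seed), and the default seed everywhere is 1753.

## Behavioural statistics

`rm_anova()` performs the one-way within-subject decomposition
($SS_{total} = SS_{line} + SS_{subject} + SS_{error}$), estimates the
Greenhouse–Geisser epsilon from the eigenvalues of the double-centered
covariance of the conditions,
$\hat\varepsilon = (\sum\lambda)^2 / \big((k-1)\sum\lambda^2\big)$,
clamped to $[1/(k-1), 1]$, and tests
$F = MS_{line}/MS_{error}$ at the $\varepsilon$-adjusted degrees of
freedom. The effect size is the generalized eta squared for this design,
$SS_{line}/(SS_{line}+SS_{subject}+SS_{error})$. Greenhouse–Geisser (not
Huynh–Feldt) is used because published adjusted dfs of the form
$F(3.44, 237.6)$ with $k = 7$, $n = 70$ imply $\varepsilon \approx 0.573$,
the GG-typical range, and GG is the conventional default. Two properties
are worth keeping in mind: with $k = 2$ the epsilon is exactly 1, and
under a covariance that is already spherical the GG-adjusted test is
*conservative* (observed type-I error ≈ 3 % at $n = 20$) — its nominal 5 %
calibration holds in the sphericity-violating regime it was designed for,
which is how the package's calibration checks simulate their null
(AR(1) correlation 0.9 across conditions, SDs from 5 to 20).

`pairwise_vs_reference()` runs paired t-tests of a reference line against
every other line with Bonferroni adjustment ($p_{adj} = \min(1, m\,p)$,
$m = k-1$). If a comparison's differences are all exactly zero the test
reports $t = 0,\ p = 1$ (identical ratings carry no evidence); a constant
nonzero difference leaves $t$ undefined and raises an error.

`choice_maxrating_correlation()` computes the Pearson correlation between
the chosen line number and the maximum-rated line number across subjects,
with $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. A subject whose maximum
rating is tied across lines contributes the mean of the tied line numbers
(the neutral convention; how ties were historically handled is unknown).
An `exclude_subjects` argument supports the with/without-exclusion
contrast for subjects whose choice and ratings disagree grossly; they are
retained by default.

## What the simulations do and do not show

The generators emulate: an ordered family of S-lines spanning the printed
RC range; subpixel digitization noise; between-subject level differences;
trial-level rating noise; and a choice rule coupled to the subject's own
ratings. They do not emulate: the extra inflections of the most complex
historical lines (lines 6–7 are matched in RC only, not in three-lobe
geometry); line thickness, arc-length or upper/lower-arc asymmetries that
covary with RC in the engraving; sequential/context effects of the
scrolling choice task; or non-Gaussian rating behaviour (floor/ceiling
users). Passing tests therefore demonstrate the correctness and
calibration of the estimators under the stated model, not the
reproduction of the historical behavioural data, whose raw form was never
published.

## A worked example

```{r example}
fam <- make_line_family()
round(attr(fam, "rc"), 1)

poly <- digitize(fam[[4]], 400, jitter_sd = 0.25, seed = 11)
fit <- fit_composite(poly, n_segments = 2)
fit
summarize_curvature(curvature_profile(fit$curve))

cfg <- experiment_config(seed = 1753)
dat <- simulate_choices(cfg, simulate_ratings(cfg))
tally_choices(dat)
rm_anova(dat)

bfit <- fit_quadratic_beauty(
  data.frame(rc = cfg$rcs, mean_rating = mean_ratings(dat)$mean))
summary(bfit)
peak_rc(bfit)
```

```{r plot}
plot(bfit)
```

## Known limitations

* The fitter assumes an ordered, open polyline; closed curves and
  unordered point clouds are out of scope.
* RC depends on the sampling density of the profile; compare values only
  at equal `n_samples`.
* The multistart heuristic is effective for 1–4 segments; many-segment
  spline fitting would want knot-insertion strategies instead.
* Curvature-equality at joins is enforced by penalty, not eliminated
  exactly; residual gaps are ~10^-8 px^-1, negligible at stimulus scale
  but not identically zero.
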