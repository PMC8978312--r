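# Quadratic curvature-preference model: mean beauty as a concave quadratic
# in the mean absolute radius of curvature (RC), the classic inverted-U
# account of curvature preference,
#
#   B = a0 + a1 * RC + a2 * RC^2,
#
# fitted by ordinary least squares on per-line mean ratings.

#' Fit the quadratic curvature-beauty model
#'
#' Regresses mean beauty ratings on the raw RC value and its square by
#' ordinary least squares. Coefficient standard errors, t statistics and
#' two-sided p values use the residual variance with n - 3 degrees of
#' freedom; the overall F test has (2, n - 3) degrees of freedom. RC is
#' used uncentered so the coefficients keep the natural pixel scale; a
#' warning is issued when the design matrix is numerically ill-conditioned.
#'
#' @param data A data frame with columns `rc` (mean absolute radius of
#'   curvature, px, all positive) and `mean_rating` (mean beauty rating),
#'   one row per line; or a numeric vector of RC values if `rating` is
#'   given separately.
#' @param rating Optional numeric vector of mean ratings, used when `data`
#'   is a plain RC vector.
#' @return An object of class `beauty_fit`: a list with `coefficients`
#'   (a0, a1, a2), `se`, `t_stats`, `p_values`, `r_squared`, `f_stat`,
#'   `f_df` (c(2, n - 3)), `fitted`, `residuals`, `df_residual` and the
#'   model frame `data`.
#' @examples
#' rc <- c(108, 109, 98, 66, 59, 48, 48)
#' b <- -109 + 4.98 * rc - 0.033 * rc^2
#' fit <- fit_quadratic_beauty(data.frame(rc = rc, mean_rating = b))
#' coef(fit)
#' peak_rc(fit)
#' @export
fit_quadratic_beauty <- function(data, rating = NULL) {
  if (is.numeric(data) && !is.null(rating))
    data <- data.frame(rc = data, mean_rating = rating)
  if (!all(c("rc", "mean_rating") %in% names(data)))
    stop("data needs columns 'rc' and 'mean_rating'")
  rc <- as.numeric(data$rc)
  b <- as.numeric(data$mean_rating)
  n <- length(rc)
  if (n < 4) stop("need at least 4 (rc, rating) pairs to fit a quadratic")
  if (any(rc <= 0)) stop("rc values must be positive")
  if (length(unique(rc)) < 3)
    stop("rank-deficient design: need at least 3 distinct rc values")

  X <- cbind(`(Intercept)` = 1, rc = rc, rc2 = rc^2)
  kap <- kappa(X, exact = TRUE)
  if (kap > 1e10)
    warning(sprintf("ill-conditioned design (condition number %.2g); consider rescaling rc", kap))
  ls <- lm.fit(X, b)
  est <- ls$coefficients
  res <- ls$residuals
  df <- n - 3L
  sigma2 <- sum(res^2) / df
  XtXi <- chol2inv(ls$qr$qr[1:3, 1:3, drop = FALSE])
  se <- sqrt(sigma2 * diag(XtXi))
  tval <- est / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  sst <- sum((b - mean(b))^2)
  ssr <- sum(res^2)
  r2 <- 1 - ssr / sst
  fstat <- ((sst - ssr) / 2) / (ssr / df)
  names(est) <- names(se) <- names(tval) <- names(pval) <- c("a0", "a1", "a2")
  structure(list(coefficients = est, se = se, t_stats = tval, p_values = pval,
                 r_squared = r2, f_stat = fstat, f_df = c(2L, df),
                 fitted = ls$fitted.values, residuals = res,
                 df_residual = df, sigma = sqrt(sigma2),
                 data = data.frame(rc = rc, mean_rating = b)),
            class = "beauty_fit")
}

#' @export
print.beauty_fit <- function(x, ...) {
  cat("Quadratic curvature-beauty model: B = a0 + a1*RC + a2*RC^2\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared %.3f, F(%d, %d) = %.2f\n",
              x$r_squared, x$f_df[1], x$f_df[2], x$f_stat))
  invisible(x)
}

#' @export
summary.beauty_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. error` = object$se,
               t = object$t_stats, p = object$p_values)
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 f_stat = object$f_stat, f_df = object$f_df,
                 sigma = object$sigma, df_residual = object$df_residual),
            class = "summary.beauty_fit")
}

#' @export
print.summary.beauty_fit <- function(x, ...) {
  cat("Quadratic curvature-beauty model\n\n")
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE,
               digits = 4)
  cat(sprintf("\nResidual sd %.3f on %d df; R-squared %.3f; F(%d, %d) = %.2f, p = %.4g\n",
              x$sigma, x$df_residual, x$r_squared, x$f_df[1], x$f_df[2],
              x$f_stat,
              pf(x$f_stat, x$f_df[1], x$f_df[2], lower.tail = FALSE)))
  invisible(x)
}

#' @export
coef.beauty_fit <- function(object, ...) object$coefficients

#' @export
fitted.beauty_fit <- function(object, ...) object$fitted

#' @export
residuals.beauty_fit <- function(object, ...) object$residuals

#' Predict mean beauty from RC
#'
#' @param object A `beauty_fit`.
#' @param rc RC value(s), px. Defaults to the fitted values' RCs.
#' @param ... Ignored.
#' @return Predicted mean rating(s), `a0 + a1*rc + a2*rc^2`.
#' @export
predict.beauty_fit <- function(object, rc = NULL, ...) {
  if (is.null(rc)) return(object$fitted)
  a <- object$coefficients
  a[1] + a[2] * rc + a[3] * rc^2
}

#' RC at the preference peak
#'
#' The vertex of the fitted parabola, -a1 / (2 a2): the radius of curvature
#' at which predicted beauty is maximal. Only defined for a concave fit.
#'
#' @param fit A `beauty_fit`, or a named coefficient vector `(a0, a1, a2)`.
#' @return Peak RC in px.
#' @export
peak_rc <- function(fit) {
  a <- if (inherits(fit, "beauty_fit")) fit$coefficients else fit
  if (length(a) != 3) stop("need three coefficients (a0, a1, a2)")
  if (a[3] >= 0)
    stop("no interior maximum: the quadratic coefficient is not negative")
  unname(-a[2] / (2 * a[3]))
}

#' @export
plot.beauty_fit <- function(x, ...) {
  d <- x$data
  rng <- range(d$rc)
  grid <- seq(rng[1] - 0.05 * diff(rng), rng[2] + 0.05 * diff(rng),
              length.out = 200)
  plot(d$rc, d$mean_rating, pch = 16, xlab = "RC (px)",
       ylab = "mean beauty rating", ...)
  lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Simulate rating datasets from a fitted beauty model
#'
#' Generates complete rating/choice experiments whose population means
#' follow the fitted quadratic at the model's RC values (see
#' [simulate_ratings()] for the noise structure).
#'
#' @param object A `beauty_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param n_subjects,subject_sd,noise_sd,choice_concentration Passed to
#'   [experiment_config()].
#' @param ... Ignored.
#' @return A list of `rating_dataset` objects (length `nsim`).
#' @export
simulate.beauty_fit <- function(object, nsim = 1, seed = NULL,
                                n_subjects = 70, subject_sd = 10,
                                noise_sd = 15, choice_concentration = 0.2,
                                ...) {
  a <- object$coefficients
  if (is.null(seed)) seed <- 1753L
  lapply(seq_len(nsim), function(i) {
    cfg <- experiment_config(a0 = a[1], a1 = a[2], a2 = a[3],
                             rcs = object$data$rc, n_subjects = n_subjects,
                             subject_sd = subject_sd, noise_sd = noise_sd,
                             choice_concentration = choice_concentration,
                             seed = seed + i - 1L)
    d <- simulate_ratings(cfg)
    d$choices <- simulate_choices(cfg, d)$choices
    d
  })
}
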