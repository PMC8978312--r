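# Behavioural statistics for rating/choice experiments on line stimuli:
# choice tallies, per-line means and standard errors, one-way
# repeated-measures ANOVA with Greenhouse-Geisser correction and
# generalized eta squared, Bonferroni-adjusted paired comparisons against
# a reference line, and the choice/maximum-rating correlation.

#' Bundle ratings and choices into a rating dataset
#'
#' @param ratings Data frame with columns `subject`, `line`, `rating`; one
#'   row per subject x line, ratings on the 1-100 visual-analog scale.
#' @param choices Optional data frame with columns `subject`, `choice`
#'   (chosen line id), one row per subject.
#' @return An object of class `rating_dataset`.
#' @export
rating_dataset <- function(ratings, choices = NULL) {
  ratings <- as.data.frame(ratings)
  if (!all(c("subject", "line", "rating") %in% names(ratings)))
    stop("ratings needs columns subject, line, rating")
  if (any(ratings$rating < 1 | ratings$rating > 100))
    stop("ratings must lie on the 1-100 scale")
  if (anyDuplicated(ratings[c("subject", "line")]))
    stop("each (subject, line) pair may appear only once")
  if (!is.null(choices)) {
    choices <- as.data.frame(choices)
    if (!all(c("subject", "choice") %in% names(choices)))
      stop("choices needs columns subject, choice")
    if (!all(choices$subject %in% ratings$subject))
      stop("every choice subject must appear in the ratings")
  }
  structure(list(ratings = ratings, choices = choices),
            class = "rating_dataset")
}

#' @export
print.rating_dataset <- function(x, ...) {
  cat(sprintf("Rating dataset: %d subjects x %d lines%s\n",
              length(unique(x$ratings$subject)),
              length(unique(x$ratings$line)),
              if (is.null(x$choices)) "" else
                sprintf(", %d choices", nrow(x$choices))))
  invisible(x)
}

# n x k matrix of ratings (subjects x lines), erroring on missing cells
rating_matrix <- function(data) {
  r <- data$ratings
  lines <- sort(unique(r$line))
  subjects <- unique(r$subject)
  m <- tapply(r$rating, list(factor(r$subject, subjects),
                             factor(r$line, lines)), identity)
  if (anyNA(m)) stop("incomplete design: every subject must rate every line")
  storage.mode(m) <- "double"
  m
}

#' Tally forced choices per line
#'
#' @param data A `rating_dataset` with choices.
#' @return Named integer vector of counts, one entry per line present in
#'   the ratings (0 for lines never chosen).
#' @export
tally_choices <- function(data) {
  if (is.null(data$choices) || nrow(data$choices) == 0)
    stop("no choices present")
  lines <- sort(unique(data$ratings$line))
  table(factor(data$choices$choice, levels = lines))
}

#' Per-line mean ratings and standard errors
#'
#' @param data A `rating_dataset`.
#' @return Data frame with columns `line`, `mean`, `se` (sd / sqrt(n)) and
#'   `n`.
#' @export
mean_ratings <- function(data) {
  m <- rating_matrix(data)
  data.frame(line = as.numeric(colnames(m)),
             mean = colMeans(m),
             se = apply(m, 2, sd) / sqrt(nrow(m)),
             n = nrow(m), row.names = NULL)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Decomposes the total sum of squares of a complete subjects x lines
#' rating table into condition, subject and error components. The
#' Greenhouse-Geisser epsilon is estimated from the eigenvalues of the
#' double-centered covariance matrix of the conditions,
#' epsilon = (sum lambda)^2 / ((k - 1) sum lambda^2), and the F test uses
#' the epsilon-adjusted degrees of freedom. The effect size is the
#' generalized eta squared SS_condition / (SS_condition + SS_subject +
#' SS_error).
#'
#' @param data A `rating_dataset` (complete and balanced).
#' @return An object of class `rm_anova` with the sums of squares, raw and
#'   adjusted degrees of freedom, `epsilon`, `f_stat`, `p_value` and `ges`.
#' @export
rm_anova <- function(data) {
  m <- rating_matrix(data)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("need at least 2 lines")
  if (n < 3) stop("need at least 3 subjects")
  gm <- mean(m)
  ss_total <- sum((m - gm)^2)
  ss_subject <- k * sum((rowMeans(m) - gm)^2)
  ss_condition <- n * sum((colMeans(m) - gm)^2)
  ss_error <- ss_total - ss_subject - ss_condition
  df_condition <- k - 1L
  df_subject <- n - 1L
  df_error <- (k - 1L) * (n - 1L)
  ms_condition <- ss_condition / df_condition
  ms_error <- ss_error / df_error
  f_stat <- ms_condition / ms_error
  # Greenhouse-Geisser epsilon from the double-centered condition covariance
  S <- cov(m)
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  lambda <- eigen(Sdc, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  epsilon <- sum(lambda)^2 / ((k - 1) * sum(lambda^2))
  epsilon <- min(max(epsilon, 1 / (k - 1)), 1)
  df_adj <- epsilon * c(df_condition, df_error)
  p_value <- pf(f_stat, df_adj[1], df_adj[2], lower.tail = FALSE)
  ges <- ss_condition / (ss_condition + ss_subject + ss_error)
  structure(list(ss_condition = ss_condition, ss_subject = ss_subject,
                 ss_error = ss_error,
                 df_condition = df_condition, df_subject = df_subject,
                 df_error = df_error,
                 epsilon = epsilon, f_stat = f_stat, df_adj = df_adj,
                 p_value = p_value, ges = ges,
                 n_subjects = n, n_lines = k),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("One-way repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  cat(sprintf("  F(%.2f, %.1f) = %.2f, p = %.4g, GES = %.3f (epsilon = %.3f)\n",
              x$df_adj[1], x$df_adj[2], x$f_stat, x$p_value, x$ges,
              x$epsilon))
  cat(sprintf("  SS condition %.2f (df %d), subject %.2f (df %d), error %.2f (df %d)\n",
              x$ss_condition, x$df_condition, x$ss_subject, x$df_subject,
              x$ss_error, x$df_error))
  invisible(x)
}

#' Paired comparisons of one line against all others
#'
#' Paired t tests of the reference line's ratings against each other
#' line's, with Bonferroni adjustment over the k - 1 comparisons.
#'
#' @param data A `rating_dataset` (complete).
#' @param reference Reference line id (default 4).
#' @return Data frame with columns `line`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
pairwise_vs_reference <- function(data, reference = 4) {
  m <- rating_matrix(data)
  lines <- as.numeric(colnames(m))
  if (!reference %in% lines) stop("reference line not present")
  others <- lines[lines != reference]
  ref <- m[, as.character(reference)]
  rows <- lapply(others, function(l) {
    d <- ref - m[, as.character(l)]
    if (sd(d) == 0) {
      # identical ratings give no evidence (t = 0); a constant nonzero
      # difference has no within-pair variability and t is undefined
      if (all(d == 0))
        return(data.frame(line = l, t = 0, df = length(d) - 1L, p_raw = 1))
      stop(sprintf("zero-variance differences against line %s: t undefined", l))
    }
    tt <- t.test(ref, m[, as.character(l)], paired = TRUE)
    data.frame(line = l, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_raw, method = "bonferroni")
  out
}

# Line number with the maximum rating; ties resolved as the mean of the
# tied line numbers.
max_rated_line <- function(ratings_row, lines) {
  mx <- max(ratings_row)
  mean(lines[ratings_row == mx])
}

#' Correlation between chosen line and maximum-rated line
#'
#' Pearson correlation, across subjects, between the number of the chosen
#' line and the number of the line each subject rated highest (ties
#' resolved as the mean of the tied line numbers). Significance by
#' t = r sqrt(n - 2) / sqrt(1 - r^2) with n - 2 degrees of freedom.
#'
#' @param data A `rating_dataset` with choices.
#' @param exclude_subjects Optional vector of subject ids to drop before
#'   computing the correlation (e.g. subjects whose choice and ratings
#'   disagree grossly).
#' @return A list with `r`, `t`, `df`, `p`, `n`.
#' @export
choice_maxrating_correlation <- function(data, exclude_subjects = NULL) {
  if (is.null(data$choices)) stop("no choices present")
  m <- rating_matrix(data)
  lines <- as.numeric(colnames(m))
  subj <- rownames(m)
  ch <- data$choices
  chosen <- ch$choice[match(subj, ch$subject)]
  if (anyNA(chosen)) stop("every rating subject needs a choice")
  maxline <- apply(m, 1, max_rated_line, lines = lines)
  if (!is.null(exclude_subjects)) {
    keep <- !(subj %in% as.character(exclude_subjects))
    chosen <- chosen[keep]; maxline <- maxline[keep]
  }
  n <- length(chosen)
  if (sd(chosen) == 0 || sd(maxline) == 0)
    stop("zero variance: correlation undefined")
  r <- cor(chosen, maxline)
  t <- correlation_t(r, n)
  list(r = r, t = t, df = n - 2L,
       p = 2 * pt(abs(t), n - 2, lower.tail = FALSE), n = n)
}

#' t statistic for a Pearson correlation
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations.
#' @return `r * sqrt(n - 2) / sqrt(1 - r^2)`, on n - 2 degrees of freedom.
#' @export
correlation_t <- function(r, n) r * sqrt(n - 2) / sqrt(1 - r^2)
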