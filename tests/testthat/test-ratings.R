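test_that("choice tallies count every line and ignore row order", {
  cfg <- experiment_config(n_subjects = 70, seed = 8)
  d <- simulate_choices(cfg, simulate_ratings(cfg))
  tc <- tally_choices(d)
  expect_equal(sum(tc), 70)
  expect_length(tc, 7)
  shuffled <- d
  shuffled$choices <- d$choices[sample(nrow(d$choices)), ]
  expect_equal(tally_choices(shuffled), tc)
  # unanimous choices
  allfour <- d
  allfour$choices$choice <- 4
  t4 <- tally_choices(allfour)
  expect_equal(unname(t4[["4"]]), 70)
  expect_equal(sum(t4), 70)
})

test_that("per-line means and standard errors follow hand arithmetic", {
  m <- matrix(50, 5, 3)
  mr <- mean_ratings(toy_ratings(m))
  expect_equal(mr$mean, rep(50, 3))
  expect_equal(mr$se, rep(0, 3))
  two <- toy_ratings(matrix(c(40, 60, 40, 60), 2, 2))
  mr2 <- mean_ratings(two)
  expect_equal(mr2$mean, c(50, 50))
  expect_equal(mr2$se, c(10, 10))
  # simulated means sit within 3 standard errors of the model means
  cfg <- experiment_config(n_subjects = 70, noise_sd = 5, subject_sd = 0,
                           seed = 10)
  mr3 <- mean_ratings(simulate_ratings(cfg))
  expect_true(all(abs(mr3$mean - model_means(cfg)) < 3 * 5 / sqrt(70)))
})

test_that("rm_anova reproduces a brute-force sums-of-squares decomposition", {
  m <- matrix(c(6, 4, 5, 7,
                8, 7, 7, 9,
                5, 5, 6, 8), 4, 3) * 10 - 20
  a <- rm_anova(toy_ratings(m))
  gm <- mean(m)
  ss_t <- sum((m - gm)^2)
  ss_s <- 3 * sum((rowMeans(m) - gm)^2)
  ss_c <- 4 * sum((colMeans(m) - gm)^2)
  expect_equal(a$ss_condition, ss_c, tolerance = 1e-10)
  expect_equal(a$ss_subject, ss_s, tolerance = 1e-10)
  expect_equal(a$ss_error, ss_t - ss_s - ss_c, tolerance = 1e-10)
  expect_equal(a$df_condition, 2L)
  expect_equal(a$df_error, 6L)
  expect_equal(a$f_stat, (ss_c / 2) / ((ss_t - ss_s - ss_c) / 6),
               tolerance = 1e-10)
  expect_equal(a$ges, ss_c / ss_t, tolerance = 1e-10)
  # cross-check against aov's within-subject stratum
  df <- toy_ratings(m)$ratings
  df$subject <- factor(df$subject); df$line <- factor(df$line)
  av <- summary(aov(rating ~ line + Error(subject), data = df))
  tab <- av[["Error: Within"]][[1]]
  expect_equal(a$f_stat, tab[["F value"]][1], tolerance = 1e-10)
  # SS partition identity on simulated data
  for (s in 1:5) {
    d <- simulate_ratings(experiment_config(n_subjects = 15, seed = s))
    aa <- rm_anova(d)
    mm <- hogarth:::rating_matrix(d)
    expect_equal(aa$ss_condition + aa$ss_subject + aa$ss_error,
                 sum((mm - mean(mm))^2), tolerance = 1e-6)
  }
})

test_that("Greenhouse-Geisser epsilon has the right bounds and limits", {
  # two conditions: epsilon is exactly 1
  set.seed(41)
  m2 <- matrix(rnorm(40, 50, 10), 20, 2)
  expect_equal(rm_anova(toy_ratings(pmin(pmax(m2, 1), 100)))$epsilon, 1)
  # compound symmetry: epsilon = 1 (constructed, near-exact sample version)
  n <- 2000; k <- 4
  set.seed(42)
  subj <- rnorm(n, 0, 5)
  m <- 50 + outer(subj, rep(1, k)) + matrix(rnorm(n * k, 0, 3), n, k)
  eps <- rm_anova(toy_ratings(pmin(pmax(m, 1), 100)))$epsilon
  expect_gt(eps, 0.98)
  # always within [1/(k-1), 1]
  for (s in 1:5) {
    d <- simulate_ratings(experiment_config(n_subjects = 10, seed = 100 + s))
    e <- rm_anova(d)$epsilon
    expect_gte(e, 1 / 6)
    expect_lte(e, 1)
  }
  # the published adjusted dfs are consistent with a GG epsilon
  eps_printed <- 3.44 / 6
  expect_equal(eps_printed * 6 * 69, 237.4, tolerance = 0.5)
})

test_that("rm_anova rejects incomplete or tiny designs", {
  d <- simulate_ratings(experiment_config(n_subjects = 5, seed = 1))
  d$ratings <- d$ratings[-3, ]
  expect_error(rm_anova(d), "incomplete")
  tiny <- toy_ratings(matrix(c(1, 2, 3, 4), 2, 2))
  expect_error(rm_anova(tiny), "3 subjects")
})

test_that("paired comparisons are Bonferroni-adjusted and monotone", {
  cfg <- experiment_config(n_subjects = 70, seed = 17)
  d <- simulate_ratings(cfg)
  pw <- pairwise_vs_reference(d, reference = 4)
  expect_equal(nrow(pw), 6)
  expect_equal(pw$p_adj, pmin(1, 6 * pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_equal(order(pw$p_adj), order(pw$p_raw))
  expect_true(all(pw$df == 69))
  # paired t against base R for one pair
  m <- hogarth:::rating_matrix(d)
  tt <- t.test(m[, "4"], m[, "1"], paired = TRUE)
  expect_equal(pw$t[pw$line == 1], unname(tt$statistic))
  # identical ratings: no evidence, capped p
  base <- matrix(c(30, 40, 50, 60, 35, 52, 48, 61), 4, 2)
  m2 <- cbind(base, base[, 1])
  colnames(m2) <- 1:3
  pw2 <- pairwise_vs_reference(toy_ratings(m2), reference = 1)
  expect_equal(pw2$t[pw2$line == 3], 0)
  expect_equal(pw2$p_adj[pw2$line == 3], 1)
  # constant nonzero difference: undefined t
  m3 <- cbind(base, base[, 1] + 2)
  colnames(m3) <- 1:3
  expect_error(pairwise_vs_reference(toy_ratings(m3), 1), "undefined")
  # a large raw p is capped at 1 after adjustment
  expect_true(all(pw$p_adj[pw$p_raw > 1 / 6] == 1))
})

test_that("choice/max-rating correlation follows the t transform", {
  expect_equal(correlation_t(0.387, 70), 3.46, tolerance = 0.005)
  expect_equal(correlation_t(0.743, 61), 8.52, tolerance = 0.005)
  expect_equal(correlation_t(0, 50), 0)
  cfg <- experiment_config(n_subjects = 70, seed = 23,
                           choice_concentration = 1)
  d <- simulate_choices(cfg, simulate_ratings(cfg))
  ct <- choice_maxrating_correlation(d)
  expect_equal(ct$df, 68)
  expect_equal(ct$t, ct$r * sqrt(68) / sqrt(1 - ct$r^2))
  expect_equal(ct$p, 2 * pt(abs(ct$t), 68, lower.tail = FALSE))
  # excluding subjects changes n and (generically) r
  ex <- choice_maxrating_correlation(d, exclude_subjects = 1:9)
  expect_equal(ex$n, 61)
  # deterministic choice of the own maximum gives r = 1 up to ties
  cfg2 <- experiment_config(n_subjects = 40, seed = 29,
                            choice_concentration = Inf)
  d2 <- simulate_choices(cfg2, simulate_ratings(cfg2))
  expect_gt(choice_maxrating_correlation(d2)$r, 0.99)
})

test_that("rating_dataset validates its invariants", {
  expect_error(rating_dataset(data.frame(subject = 1, line = 1,
                                         rating = 120)), "1-100")
  expect_error(rating_dataset(data.frame(subject = c(1, 1),
                                         line = c(2, 2),
                                         rating = c(10, 20))), "once")
  d <- simulate_ratings(experiment_config(n_subjects = 5, seed = 2))
  expect_error(rating_dataset(d$ratings,
                              data.frame(subject = 99, choice = 4)),
               "appear in the ratings")
})
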