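test_that("wave ordering and time codings follow mission-month labels", {
  w <- c("M9", "M1", "M6", "M3")
  expect_equal(wave_order(w), c("M1", "M3", "M6", "M9"))
  expect_equal(wave_time(w), c(3, 0, 2, 1))
  expect_equal(wave_time(w, "month"), c(8, 0, 5, 2))
  expect_equal(wave_time(c("b", "a"), "wave_index"), c(1, 0))
  expect_error(wave_time(c("b", "a"), "month"), "numeric wave labels")
})

test_that("rm_anova matches the sums-of-squares oracle and aov dfs", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:12, 1); w <- sample(3:4, 1)
    mat <- matrix(rnorm(n * w, mean = 30, sd = 5), n, w)
    res <- rm_anova(panel_from_matrix(mat), "y")
    ora <- rm_anova_oracle(mat)
    expect_equal(res$F, ora$F, tolerance = 1e-10)
    expect_equal(res$df_num, ora$df1)
    expect_equal(res$df_den, ora$df2)
    expect_equal(res$n_complete, n)
    expect_equal(res$p, stats::pf(ora$F, ora$df1, ora$df2,
                                  lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("rm_anova is invariant to person-constant shifts and drops incomplete cases", {
  set.seed(22)
  mat <- matrix(rnorm(24, 30, 4), 6, 4)
  base <- rm_anova(panel_from_matrix(mat), "y")
  shifted <- mat + rnorm(6, sd = 10)  # add a person-specific constant
  expect_equal(rm_anova(panel_from_matrix(shifted), "y")$F, base$F,
               tolerance = 1e-9)
  # equal wave means: no time effect, F = 0
  flat <- matrix(rnorm(20, 30, 4), 5, 4)
  flat <- sweep(flat, 2, colMeans(flat)) + 30
  expect_equal(rm_anova(panel_from_matrix(flat), "y")$F, 0, tolerance = 1e-9)
  # a person missing one wave is listwise-deleted
  p <- panel_from_matrix(mat)
  p <- p[!(p$person_id == "P1" & p$wave == "M2"), ]
  res <- rm_anova(p, "y")
  expect_equal(res$n_complete, 5)
  expect_equal(res$F, rm_anova_oracle(mat[-1, ])$F, tolerance = 1e-10)
  tiny <- panel_from_matrix(mat[1:2, ])
  expect_error(rm_anova(tiny, "y"), "3 complete")
})

test_that("paired_t reproduces a textbook example and sign convention", {
  mat <- cbind(c(10, 12, 14), c(11, 13, 15))  # uniform +1 increase
  colnames(mat) <- NULL
  p <- panel_from_matrix(mat, waves = c("M3", "M6"))
  r <- paired_t(p, "y", "M3", "M6")
  # d = a - b = -1 each; sd 0 -> degenerate -Inf
  expect_true(r$degenerate)
  expect_equal(r$t, -Inf)
  expect_equal(r$p, 0)

  mat2 <- cbind(c(1, 2, 3), c(0, 0, 0))
  p2 <- panel_from_matrix(mat2, waves = c("M3", "M6"))
  r2 <- paired_t(p2, "y", "M3", "M6")
  # d = (1,2,3): t = mean/ (sd/sqrt(n)) = 2 / (1/sqrt(3)) = 3.4641
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r2$df, 2)
  expect_equal(r2$n, 3)
  expect_equal(r2$mean_a, 2)
  expect_equal(r2$sd_b, 0)
  # antisymmetry in the wave arguments
  r2r <- paired_t(p2, "y", "M6", "M3")
  expect_equal(r2r$t, -r2$t)
  expect_equal(r2r$p, r2$p)
  # one-sided p is half the two-sided p
  expect_equal(paired_t(p2, "y", "M3", "M6", tail = "one")$p, r2$p / 2)
  # only persons observed at both waves are used
  p3 <- rbind(p2, data.frame(person_id = "P9", wave = "M3",
                             outcome = "y", score = 5))
  expect_equal(paired_t(p3, "y", "M3", "M6")$n, 3)
})

test_that("fit_growth recovers a noise-free linear trend exactly", {
  waves <- c("M1", "M3", "M6", "M9")
  intercepts <- c(20, 25, 30, 35, 40)
  slopes <- c(1, 2, 3, 4, 5)
  mat <- outer(seq_len(5), 0:3, function(i, t) intercepts[i] + slopes[i] * t)
  fit <- fit_growth(panel_from_matrix(mat, waves = waves), "y")
  expect_s3_class(fit, "growth_fit")
  expect_equal(fit$slope_estimate, mean(slopes), tolerance = 1e-6)
  expect_equal(fit$intercept, mean(intercepts), tolerance = 1e-6)
  expect_equal(fit$n_persons, 5)
  expect_equal(fit$n_observations, 20)
  expect_equal(unname(coef(fit)), c(mean(intercepts), mean(slopes)),
               tolerance = 1e-6)
  # data exactly linear in mission month is recovered under month coding
  months <- c(0, 2, 5, 8)
  mat_m <- outer(seq_len(5), months,
                 function(i, m) intercepts[i] + slopes[i] * m)
  fit_m <- fit_growth(panel_from_matrix(mat_m, waves = waves), "y",
                      time_coding = "month")
  expect_equal(fit_m$slope_estimate, mean(slopes), tolerance = 1e-5)
  expect_equal(fit_m$time_coding, "month")
})

test_that("balanced ML fixed slope equals the mean of per-person OLS slopes", {
  set.seed(31)
  for (rep in 1:3) {
    mat <- matrix(rnorm(48, 30, 3), 12, 4) +
      outer(rnorm(12, 0, 2), 0:3) # random person slopes
    panel <- panel_from_matrix(mat)
    fit <- fit_growth(panel, "y")
    ols <- apply(mat, 1, function(y) stats::cov(0:3, y) / stats::var(0:3))
    expect_equal(fit$slope_estimate, mean(ols), tolerance = 1e-6)
  }
})

test_that("fit_growth is equivariant under affine score transforms", {
  set.seed(32)
  mat <- matrix(rnorm(40, 25, 4), 10, 4) + outer(rnorm(10, 1, 0.5), 0:3)
  f1 <- fit_growth(panel_from_matrix(mat), "y")
  f2 <- fit_growth(panel_from_matrix(3 * mat + 7), "y")
  expect_equal(f2$slope_estimate, 3 * f1$slope_estimate, tolerance = 1e-5)
  expect_equal(f2$intercept, 3 * f1$intercept + 7, tolerance = 1e-5)
})

test_that("degenerate random-slope variance triggers the documented fallback", {
  # identical growth for everyone: zero slope variance, fit is singular
  mat <- outer(rnorm(8, 30, 5), rep(1, 4)) + outer(rep(1, 8), 2 * (0:3))
  fit <- fit_growth(panel_from_matrix(mat), "y")
  expect_false(fit$random_slope)
  expect_match(fit$fallback_reason, "degenerate|singular|converge")
  expect_equal(fit$slope_estimate, 2, tolerance = 1e-6)
  expect_error(fit_growth(panel_from_matrix(mat[1:2, ]), "y"), "3 persons")
})

test_that("bootstrap CI is deterministic in the seed and brackets the slope", {
  set.seed(33)
  mat <- matrix(rnorm(48, 30, 3), 12, 4) + outer(rnorm(12, 2, 1), 0:3)
  panel <- panel_from_matrix(mat)
  b1 <- bootstrap_ci(panel, "y", B = 400, seed = 7)
  b2 <- bootstrap_ci(panel, "y", B = 400, seed = 7)
  expect_identical(b1, b2)
  b3 <- bootstrap_ci(panel, "y", B = 400, seed = 8)
  expect_false(identical(b1$ci_low, b3$ci_low))
  expect_equal(b1$method, "exact_balanced_expanded")
  fit <- fit_growth(panel, "y")
  expect_lt(b1$ci_low, fit$slope_estimate)
  expect_gt(b1$ci_high, fit$slope_estimate)
  # expanded interval is wider than the plain percentile interval
  bp <- bootstrap_ci(panel, "y", B = 400, seed = 7, expand = FALSE)
  expect_lt(bp$ci_high - bp$ci_low, b1$ci_high - b1$ci_low)
  expect_equal(bp$method, "exact_balanced")
  # the calling RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(bootstrap_ci(panel, "y", B = 100, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("unbalanced panels take the mixed-model refit path", {
  set.seed(34)
  mat <- matrix(rnorm(40, 30, 3), 10, 4) + outer(rnorm(10, 2, 1), 0:3)
  panel <- panel_from_matrix(mat)
  panel <- panel[!(panel$person_id == "P1" & panel$wave == "M4"), ]
  b <- bootstrap_ci(panel, "y", B = 100, seed = 5)
  expect_equal(b$method, "lmm_refit_expanded")
  expect_lt(b$ci_low, b$ci_high)
  # both paths agree on a balanced panel to bootstrap-noise accuracy
  full <- panel_from_matrix(mat)
  exact <- bootstrap_ci(full, "y", B = 200, seed = 5)
  # force the slow path by perturbing then restoring balance is not possible
  # directly; instead check the exact path against its own definition
  d <- data.frame(score = full$score, time = wave_time(full$wave),
                  person = full$person_id)
  ols <- vapply(split(d, d$person),
                function(g) stats::cov(g$time, g$score) / stats::var(g$time),
                numeric(1))
  fit <- fit_growth(full, "y")
  expect_equal(mean(ols), fit$slope_estimate, tolerance = 1e-6)
  expect_lt(exact$ci_low, mean(ols))
})

test_that("sensitivity_exclude removes exactly one person", {
  mat <- matrix(rnorm(20, 30, 2), 5, 4)
  panel <- panel_from_matrix(mat)
  out <- sensitivity_exclude(panel, "P3")
  expect_equal(sort(unique(out$person_id)), c("P1", "P2", "P4", "P5"))
  expect_equal(nrow(out), 16)
  expect_error(sensitivity_exclude(panel, "Q9"), "unknown person")
})

test_that("growth_fit prints slope, CI and fallback status", {
  mat <- matrix(rnorm(20, 30, 2), 5, 4) + outer(rnorm(5, 1, 0.6), 0:3)
  fit <- fit_growth(panel_from_matrix(mat), "y")
  expect_output(print(fit), "slope")
  fit$ci_low <- 0.5; fit$ci_high <- 1.5
  expect_output(print(fit), "\\[0.500, 1.500\\]")
  s <- summary(fit)
  expect_s3_class(s, "summary.growth_fit")
  expect_output(print(s), "slope_estimate")
})
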