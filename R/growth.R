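# Longitudinal change over the four measurement waves: complete-case
# repeated-measures ANOVA, paired t tests, a two-level linear growth model
# (random intercept and slope, ML) fitted on all available observations, and
# person-level Monte-Carlo bootstrap confidence intervals for the growth
# slope. The growth model is the package's stand-in for a latent growth
# model: with four waves and a dozen crew members the two parameterizations
# coincide in the quantity of interest, the fixed slope of time.

wave_order <- function(waves) {
  u <- unique(as.character(waves))
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", u)))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' Numeric time codes for wave labels
#'
#' `"wave_index"` codes the waves 0, 1, 2, ... in order; `"month"` codes
#' mission-month labels (`M1, M3, M6, M9`) as months elapsed since the first
#' wave (0, 2, 5, 8).
#'
#' @param waves character wave labels.
#' @param time_coding `"wave_index"` or `"month"`.
#' @return numeric vector aligned with `waves`.
#' @export
wave_time <- function(waves, time_coding = c("wave_index", "month")) {
  time_coding <- match.arg(time_coding)
  lev <- wave_order(waves)
  if (time_coding == "wave_index") {
    return(match(as.character(waves), lev) - 1)
  }
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", lev)))
  if (anyNA(num)) stop("month coding requires numeric wave labels like 'M3'")
  (num - num[1])[match(as.character(waves), lev)]
}

panel_outcome <- function(panel, outcome) {
  sub <- panel[panel$outcome == outcome & !is.na(panel$score), , drop = FALSE]
  if (!nrow(sub)) stop("no observations for outcome '", outcome, "'")
  sub
}

#' One-way repeated-measures ANOVA for a panel outcome
#'
#' Complete-case (listwise-deleted) within-subject ANOVA with time as the
#' single factor and no sphericity correction:
#' `F = MS_time / MS_(time x subject)` with degrees of freedom
#' `(w - 1, (w - 1)(n - 1))` for `w` waves and `n` complete cases.
#'
#' @param panel long panel (`person_id`, `wave`, `outcome`, `score`).
#' @param outcome outcome name.
#' @return list of class `rm_anova`: `outcome`, `F`, `df_num`, `df_den`, `p`,
#'   `n_complete`.
#' @export
rm_anova <- function(panel, outcome) {
  sub <- panel_outcome(panel, outcome)
  waves <- wave_order(sub$wave)
  tab <- table(sub$person_id, factor(sub$wave, levels = waves))
  complete <- rownames(tab)[rowSums(tab > 0) == length(waves)]
  if (length(complete) < 3L) {
    stop("fewer than 3 complete cases for outcome '", outcome, "'")
  }
  sub <- sub[sub$person_id %in% complete, , drop = FALSE]
  d <- data.frame(score = sub$score,
                  wave = factor(sub$wave, levels = waves),
                  person = factor(sub$person_id))
  fit <- stats::aov(score ~ wave + Error(person), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  structure(list(outcome = outcome,
                 F = s["wave", "F value"],
                 df_num = s["wave", "Df"],
                 df_den = s["Residuals", "Df"],
                 p = s["wave", "Pr(>F)"],
                 n_complete = length(complete)),
            class = "rm_anova")
}

#' @exportS3Method base::print
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: %s\n  F(%d, %d) = %.3f, p = %.4g (N = %d complete)\n",
              x$outcome, x$df_num, x$df_den, x$F, x$p, x$n_complete))
  invisible(x)
}

#' Paired-samples t test between two waves
#'
#' The t statistic is computed on the within-person differences
#' `score(wave_a) - score(wave_b)` over persons observed at both waves, so an
#' increase from `wave_a` to `wave_b` yields a negative t. With
#' `tail = "one"` the reported p is the one-sided p in the direction of the
#' observed mean difference (half the two-sided p).
#'
#' @param panel long panel.
#' @param outcome outcome name.
#' @param wave_a,wave_b wave labels.
#' @param tail `"two"` (default) or `"one"`.
#' @return list: `t`, `df`, `p`, `n`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `tail`, `degenerate` (TRUE when the differences have zero variance).
#' @export
paired_t <- function(panel, outcome, wave_a, wave_b,
                     tail = c("two", "one")) {
  tail <- match.arg(tail)
  sub <- panel_outcome(panel, outcome)
  xa <- sub[sub$wave == wave_a, c("person_id", "score")]
  xb <- sub[sub$wave == wave_b, c("person_id", "score")]
  m <- merge(xa, xb, by = "person_id", suffixes = c("_a", "_b"))
  n <- nrow(m)
  if (n < 2L) stop("fewer than 2 persons observed at both waves")
  d <- m$score_a - m$score_b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p2 <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- stats::t.test(m$score_a, m$score_b, paired = TRUE)
    tt <- unname(ht$statistic)
    p2 <- ht$p.value
  }
  p <- if (tail == "two") p2 else p2 / 2
  list(t = tt, df = n - 1L, p = p, n = n,
       mean_a = mean(m$score_a), mean_b = mean(m$score_b),
       sd_a = stats::sd(m$score_a), sd_b = stats::sd(m$score_b),
       tail = tail, degenerate = degenerate)
}

#' Fit a linear growth model to a panel outcome
#'
#' Two-level linear growth model fitted by maximum likelihood on all
#' available observations (no listwise deletion):
#' `score_pt = (b0 + u0_p) + (b1 + u1_p) * time_t + e_pt`
#' with correlated person-level random intercept `u0` and slope `u1`. When
#' the random-slope variance is degenerate (singular fit) or the model fails
#' to converge, the model falls back to a random-intercept-only fit and says
#' so in the result. The slope p-value uses Satterthwaite degrees of freedom.
#'
#' @param panel long panel.
#' @param outcome outcome name.
#' @param time_coding `"wave_index"` (0,1,2,3; default) or `"month"`
#'   (0,2,5,8). The slope's units are score points per coded time unit.
#' @return object of class `growth_fit`.
#' @export
fit_growth <- function(panel, outcome,
                       time_coding = c("wave_index", "month")) {
  time_coding <- match.arg(time_coding)
  sub <- panel_outcome(panel, outcome)
  if (length(unique(sub$person_id)) < 3L) {
    stop("growth model needs at least 3 persons")
  }
  d <- data.frame(score = sub$score,
                  time = wave_time(sub$wave, time_coding),
                  person = factor(sub$person_id))
  fit <- NULL
  random_slope <- TRUE
  fallback_reason <- NULL
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(score ~ time + (time | person), data = d, REML = FALSE))),
    error = function(e) e)
  if (inherits(fit, "error") || lme4::isSingular(fit, tol = 1e-5)) {
    fallback_reason <- if (inherits(fit, "error")) {
      conditionMessage(fit)
    } else "degenerate random-slope variance"
    random_slope <- FALSE
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(score ~ time + (1 | person), data = d, REML = FALSE)))
  }
  ct <- stats::coef(summary(fit))
  structure(list(outcome = outcome,
                 intercept = ct["(Intercept)", "Estimate"],
                 slope_estimate = ct["time", "Estimate"],
                 slope_se = ct["time", "Std. Error"],
                 slope_df = ct["time", "df"],
                 slope_p = ct["time", "Pr(>|t|)"],
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_persons = nlevels(d$person),
                 n_observations = nrow(d),
                 time_coding = time_coding,
                 random_slope = random_slope,
                 fallback_reason = fallback_reason,
                 model = fit),
            class = "growth_fit")
}

#' @exportS3Method base::print
print.growth_fit <- function(x, ...) {
  cat(sprintf("Linear growth model: %s (time = %s)\n", x$outcome,
              x$time_coding))
  cat(sprintf("  slope %.3f (SE %.3f), p = %.4g; intercept %.3f\n",
              x$slope_estimate, x$slope_se, x$slope_p, x$intercept))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f]\n", x$ci_low, x$ci_high))
  }
  cat(sprintf("  %d persons, %d observations, random slope: %s\n",
              x$n_persons, x$n_observations,
              if (x$random_slope) "yes" else "no (fallback)"))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope_estimate)
}

#' @exportS3Method base::summary
summary.growth_fit <- function(object, ...) {
  out <- object[c("outcome", "intercept", "slope_estimate", "slope_se",
                  "slope_df", "slope_p", "ci_low", "ci_high", "n_persons",
                  "n_observations", "time_coding", "random_slope")]
  class(out) <- "summary.growth_fit"
  out
}

#' @exportS3Method base::print
print.summary.growth_fit <- function(x, ...) {
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# Per-person OLS slopes; for a balanced complete panel their mean equals the
# ML fixed slope of the random-coefficient model (GLS = OLS under balance).
person_slopes <- function(d) {
  vapply(split(d, d$person, drop = TRUE), function(g) {
    if (length(unique(g$time)) < 2L) return(NA_real_)
    stats::cov(g$time, g$score) / stats::var(g$time)
  }, numeric(1))
}

is_balanced_panel <- function(d) {
  tms <- split(d$time, d$person, drop = TRUE)
  ref <- sort(tms[[1]])
  length(ref) >= 2L && !anyDuplicated(ref) &&
    all(vapply(tms, function(z) identical(sort(z), ref), logical(1)))
}

#' Person-level bootstrap confidence interval for the growth slope
#'
#' Monte-Carlo bootstrap with the person as the resampling unit: all of a
#' person's waves move together. The percentile interval of the refitted
#' fixed slope over `B` resamples is returned. For balanced complete panels
#' the refitted ML slope equals the mean of the resampled persons' OLS
#' slopes, which is used as a fast exact refit; unbalanced panels refit the
#' mixed model.
#'
#' With a dozen resampling units the plain percentile interval is too narrow
#' (the bootstrap distribution's spread is deflated by `(n-1)/n` and normal
#' rather than t quantiles are implied), so by default the expanded
#' percentile interval is used: the quantile levels are widened to
#' `pnorm(-sqrt(n/(n-1)) * qt(alpha/2, n-1))`, which restores close-to-
#' nominal coverage for small crews. `expand = FALSE` gives the plain
#' percentile interval.
#'
#' @param panel long panel.
#' @param outcome outcome name.
#' @param B number of resamples (the study convention is 2,000).
#' @param seed RNG seed; the interval is reproducible under a fixed seed.
#' @param time_coding as in [fit_growth()].
#' @param level confidence level (default 0.95).
#' @param expand use the small-sample expanded percentile levels (default
#'   `TRUE`).
#' @return list: `ci_low`, `ci_high`, `B`, `seed`, `method`, `n_failed`.
#' @export
bootstrap_ci <- function(panel, outcome, B = 2000, seed = 1L,
                         time_coding = c("wave_index", "month"),
                         level = 0.95, expand = TRUE) {
  stopifnot(B >= 100)
  time_coding <- match.arg(time_coding)
  sub <- panel_outcome(panel, outcome)
  d <- data.frame(score = sub$score,
                  time = wave_time(sub$wave, time_coding),
                  person = as.character(sub$person_id))
  persons <- unique(d$person)
  n <- length(persons)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is_balanced_panel(d)) {
    sl <- person_slopes(d)[persons]
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    boots <- rowMeans(matrix(sl[idx], nrow = B))
    n_failed <- 0L
    method <- "exact_balanced"
  } else {
    rows <- split(seq_len(nrow(d)), d$person)
    boots <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      pick <- sample(persons, n, replace = TRUE)
      db <- do.call(rbind, lapply(seq_along(pick), function(k) {
        g <- d[rows[[pick[k]]], , drop = FALSE]
        g$person <- paste0("bs", k)
        g
      }))
      boots[b] <- tryCatch({
        f <- suppressWarnings(suppressMessages(
          lme4::lmer(score ~ time + (time | person), data = db,
                     REML = FALSE)))
        if (lme4::isSingular(f, tol = 1e-5)) {
          f <- suppressWarnings(suppressMessages(
            lme4::lmer(score ~ time + (1 | person), data = db,
                       REML = FALSE)))
        }
        unname(lme4::fixef(f)["time"])
      }, error = function(e) NA_real_)
    }
    n_failed <- sum(is.na(boots))
    if (n_failed > 0.10 * B) {
      stop(n_failed, " of ", B, " bootstrap refits failed")
    }
    boots <- boots[!is.na(boots)]
    method <- "lmm_refit"
  }
  alpha <- (1 - level) / 2
  if (expand) {
    alpha <- stats::pnorm(sqrt(n / (n - 1)) * stats::qt(alpha, n - 1))
  }
  q <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(ci_low = q[1], ci_high = q[2], B = B, seed = seed,
       method = if (expand) paste0(method, "_expanded") else method,
       n_failed = n_failed)
}

#' Drop one person from a panel for sensitivity re-analysis
#'
#' @param panel long panel.
#' @param person_id person to exclude.
#' @return the panel without that person's rows.
#' @export
sensitivity_exclude <- function(panel, person_id) {
  if (!person_id %in% panel$person_id) {
    stop("unknown person id: ", person_id)
  }
  out <- panel[panel$person_id != person_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}
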