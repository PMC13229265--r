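# High-level drivers: the full questionnaire analysis on a scored panel, and
# the loader that re-runs it on a deposited dataset directory.

#' Run the longitudinal questionnaire analysis on a scored panel
#'
#' For every requested outcome: complete-case repeated-measures ANOVA, linear
#' growth model (both time codings), and a person-level bootstrap CI for the
#' growth slope. The post hoc paired t test between the second and third
#' waves is run for the paranoid-thinking subscales, where mid-mission change
#' is the question of interest.
#'
#' @param panel long scored panel (`person_id`, `wave`, `outcome`, `score`).
#' @param outcomes outcomes to analyse (default: all in the panel).
#' @param B bootstrap resamples (study convention 2,000).
#' @param seed RNG seed for the bootstrap.
#' @param exclude optional person id to drop first (sensitivity analysis).
#' @return named list per outcome with elements `rm_anova`, `growth`
#'   (wave-index coding, bootstrap CI attached), `growth_month`,
#'   and, for the paranoid subscales, `paired_t_w2_w3`.
#' @export
analyze_panel <- function(panel, outcomes = NULL, B = 2000, seed = 1L,
                          exclude = NULL) {
  if (!is.null(exclude)) panel <- sensitivity_exclude(panel, exclude)
  if (is.null(outcomes)) outcomes <- unique(panel$outcome)
  res <- lapply(outcomes, function(oc) {
    out <- list()
    out$rm_anova <- tryCatch(rm_anova(panel, oc), error = function(e) e)
    g <- fit_growth(panel, oc, time_coding = "wave_index")
    ci <- bootstrap_ci(panel, oc, B = B, seed = seed,
                       time_coding = "wave_index")
    g$ci_low <- ci$ci_low; g$ci_high <- ci$ci_high
    out$growth <- g
    out$bootstrap <- ci
    out$growth_month <- fit_growth(panel, oc, time_coding = "month")
    if (oc %in% c("ideas_of_reference", "persecutory")) {
      waves <- wave_order(panel$wave[panel$outcome == oc])
      if (length(waves) >= 3L) {
        out$paired_t_w2_w3 <- paired_t(panel, oc, waves[2], waves[3])
      }
    }
    out
  })
  stats::setNames(res, outcomes)
}

#' Flatten analysis results to a tidy statistics table
#'
#' @param results output of [analyze_panel()].
#' @return data frame `outcome`, `method`, `statistic`, `df1`, `df2`, `p`,
#'   `estimate`, `ci_low`, `ci_high`, `n`.
#' @export
stats_table <- function(results) {
  rows <- list()
  for (oc in names(results)) {
    r <- results[[oc]]
    if (!inherits(r$rm_anova, "error")) {
      a <- r$rm_anova
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, method = "rm_anova", statistic = a$F,
        df1 = a$df_num, df2 = a$df_den, p = a$p, estimate = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, n = a$n_complete)
    }
    g <- r$growth
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = oc, method = "growth_wave_index",
      statistic = g$slope_estimate / g$slope_se, df1 = g$slope_df,
      df2 = NA_real_, p = g$slope_p, estimate = g$slope_estimate,
      ci_low = g$ci_low, ci_high = g$ci_high, n = g$n_persons)
    gm <- r$growth_month
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = oc, method = "growth_month",
      statistic = gm$slope_estimate / gm$slope_se, df1 = gm$slope_df,
      df2 = NA_real_, p = gm$slope_p, estimate = gm$slope_estimate,
      ci_low = NA_real_, ci_high = NA_real_, n = gm$n_persons)
    if (!is.null(r$paired_t_w2_w3)) {
      tpl <- r$paired_t_w2_w3
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, method = "paired_t_w2_w3", statistic = tpl$t,
        df1 = tpl$df, df2 = NA_real_, p = tpl$p,
        estimate = tpl$mean_a - tpl$mean_b, ci_low = NA_real_,
        ci_high = NA_real_, n = tpl$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load a deposited dataset directory and run the questionnaire analysis
#'
#' Expects a directory with either a scored `panel.csv`
#' (`person_id`, `wave`, `outcome`, `score`) or an item-level
#' `responses.csv` scored through [score_panel()]. Column names can be
#' remapped through `column_map` for deposits using different headers.
#'
#' @param dir dataset directory.
#' @param column_map named character vector mapping canonical column names to
#'   the deposit's names, e.g. `c(person_id = "subject", wave = "session")`.
#' @param scales scale definitions used when scoring item-level data.
#' @param ... passed to [analyze_panel()].
#' @return list: `panel`, `results` (from [analyze_panel()]), `stats`
#'   (tidy table).
#' @export
reproduce_deposit <- function(dir, column_map = NULL,
                              scales = default_scales("none"), ...) {
  remap <- function(d) {
    if (!is.null(column_map)) {
      for (canon in names(column_map)) {
        names(d)[names(d) == column_map[[canon]]] <- canon
      }
    }
    d
  }
  panel_path <- file.path(dir, "panel.csv")
  resp_path <- file.path(dir, "responses.csv")
  if (file.exists(panel_path)) {
    panel <- remap(utils::read.csv(panel_path, stringsAsFactors = FALSE))
    need <- c("person_id", "wave", "outcome", "score")
    if (!all(need %in% names(panel))) {
      stop("panel.csv lacks columns: ",
           paste(setdiff(need, names(panel)), collapse = ", "))
    }
  } else if (file.exists(resp_path)) {
    tmp <- tempfile(fileext = ".csv")
    utils::write.csv(remap(utils::read.csv(resp_path,
                                           stringsAsFactors = FALSE)),
                     tmp, row.names = FALSE)
    panel <- score_panel(read_responses(tmp), scales = scales)
  } else {
    stop("no panel.csv or responses.csv found under ", dir)
  }
  results <- analyze_panel(panel, ...)
  list(panel = panel, results = results, stats = stats_table(results))
}
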