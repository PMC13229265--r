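# Linking sensor-network metrics to psychological scores. Each repeated
# measure x_{p,i}(t) is decomposed into a stable person mean and a
# wave-specific deviation (person-mean centering); within-person Spearman
# correlations pool the deviations across persons and waves, across-person
# correlations use the person means.

#' Person-mean-center a long measurement panel
#'
#' Decomposes each observation into `person_mean + deviation`, exactly:
#' within every (person, measure) series the deviations sum to zero over the
#' observed waves and `person_mean + deviation` reconstructs the observation.
#' Persons with a single observed wave for a measure carry a zero deviation
#' but are excluded from within-person analyses (flagged by `n_waves`).
#'
#' @param panel long data frame `person_id`, `wave`, `measure`, `value`
#'   (missing cells simply absent). A panel with an `outcome`/`score` naming
#'   convention (as from [score_panel()]) is accepted too.
#' @return data frame with added `person_mean`, `deviation`, `n_waves`.
#' @export
person_center <- function(panel) {
  nm <- names(panel)
  if ("outcome" %in% nm && !"measure" %in% nm) {
    names(panel)[nm == "outcome"] <- "measure"
  }
  if ("score" %in% names(panel) && !"value" %in% names(panel)) {
    names(panel)[names(panel) == "score"] <- "value"
  }
  stopifnot(all(c("person_id", "wave", "measure", "value") %in% names(panel)))
  panel <- panel[!is.na(panel$value), , drop = FALSE]
  key <- paste(panel$person_id, panel$measure, sep = "\r")
  mu <- stats::ave(panel$value, key, FUN = mean)
  nw <- stats::ave(panel$value, key, FUN = length)
  single <- nw < 2
  if (any(single)) {
    warning(length(unique(key[single])),
            " person-measure series with a single wave; excluded from ",
            "within-person analyses")
  }
  panel$person_mean <- mu
  panel$deviation <- panel$value - mu
  panel$n_waves <- as.integer(nw)
  rownames(panel) <- NULL
  panel
}

spearman_test <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate (constant) vector; Spearman undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = n)
}

#' Within-person Spearman correlation of two measures
#'
#' Spearman correlation over the pooled person-mean-centered deviations of
#' the two measures, paired by (person, wave) across all persons with at
#' least two observed waves on both measures. The two-sided p-value uses the
#' large-sample t approximation.
#'
#' @param centered output of [person_center()].
#' @param measure_x,measure_y measure names.
#' @param min_pairs minimum pooled pairs (default 5).
#' @return list: `rho`, `p`, `n`.
#' @export
within_person_spearman <- function(centered, measure_x, measure_y,
                                   min_pairs = 5L) {
  m <- merge_measures(centered, measure_x, measure_y, "deviation",
                      require_multiwave = TRUE)
  if (nrow(m) < min_pairs) {
    stop("fewer than ", min_pairs, " pooled deviation pairs for ",
         measure_x, " vs ", measure_y)
  }
  spearman_test(m$x, m$y)
}

#' Across-person Spearman correlation of two measures
#'
#' Spearman correlation of the person means of the two measures, one point
#' per person.
#'
#' @inheritParams within_person_spearman
#' @param min_persons minimum persons with both means (default 5).
#' @return list: `rho`, `p`, `n`.
#' @export
across_person_spearman <- function(centered, measure_x, measure_y,
                                   min_persons = 5L) {
  m <- merge_measures(centered, measure_x, measure_y, "person_mean",
                      require_multiwave = FALSE)
  m <- m[!duplicated(m$person_id), , drop = FALSE]
  if (nrow(m) < min_persons) {
    stop("fewer than ", min_persons, " persons with both measures")
  }
  spearman_test(m$x, m$y)
}

merge_measures <- function(centered, measure_x, measure_y, value_col,
                           require_multiwave) {
  pick <- function(ms) {
    s <- centered[centered$measure == ms, , drop = FALSE]
    if (require_multiwave) s <- s[s$n_waves >= 2L, , drop = FALSE]
    data.frame(person_id = s$person_id, wave = s$wave, v = s[[value_col]],
               stringsAsFactors = FALSE)
  }
  a <- pick(measure_x); b <- pick(measure_y)
  m <- merge(a, b, by = c("person_id", "wave"), suffixes = c("_x", "_y"))
  data.frame(person_id = m$person_id, wave = m$wave, x = m$v_x, y = m$v_y,
             stringsAsFactors = FALSE)
}

#' Significance marker for a p-value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, dagger for marginal
#' p < 0.10, empty otherwise.
#'
#' @param p p-value(s).
#' @return character vector of markers.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else if (pp < 0.10) "†"
    else ""
  }, character(1))
}

#' Full correlation matrix over study measures
#'
#' Computes the Spearman correlation between every pair of measures, either
#' within-person (pooled deviations) or across-person (person means), with
#' two-sided p-values and significance markers. Diagonal entries are 1 by
#' construction for non-degenerate measures.
#'
#' @param centered output of [person_center()].
#' @param measures measure names (default: all in the panel).
#' @param scope `"within_person"` (default) or `"across_person"`.
#' @return object of class `correlation_matrix`: list with matrices `rho`,
#'   `p`, `n`, `stars`, and `scope`.
#' @export
correlation_heatmap_table <- function(centered, measures = NULL,
                                      scope = c("within_person",
                                                "across_person")) {
  scope <- match.arg(scope)
  if (is.null(measures)) measures <- unique(centered$measure)
  k <- length(measures)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  diag(rho) <- 1
  f <- if (scope == "within_person") within_person_spearman else
    across_person_spearman
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      r <- f(centered, measures[i], measures[j])
      rho[i, j] <- rho[j, i] <- r$rho
      p[i, j] <- p[j, i] <- r$p
      n[i, j] <- n[j, i] <- r$n
    }
  }
  stars <- matrix(significance_stars(p), k, k,
                  dimnames = dimnames(p))
  structure(list(rho = rho, p = p, n = n, stars = stars, scope = scope),
            class = "correlation_matrix")
}

#' @exportS3Method base::print
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlations (", x$scope, ")\n", sep = "")
  disp <- matrix(paste0(format(round(x$rho, digits)), x$stars),
                 nrow(x$rho), dimnames = dimnames(x$rho))
  diag(disp) <- "1"
  print(disp, quote = FALSE)
  invisible(x)
}
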