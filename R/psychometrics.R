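# Scoring of the five questionnaire instruments administered at each wave,
# internal-consistency (Cronbach's alpha) computation, and the severe-paranoia
# flag. Scale definitions are data, not code: reverse-keyed item sets,
# option ranges and the sum-vs-mean aggregation rule are all declared in a
# definition list so alternative keyings can be configured.

#' Default scale definitions
#'
#' The instrument battery:
#' \itemize{
#'   \item `loneliness` — UCLA Loneliness Scale, 20 items, options 1-4,
#'     summed; score range 20-80. `reverse_keys = "ucla"` applies the
#'     conventional reverse-scored item set; `"none"` assumes responses are
#'     already recoded (as deposited datasets often are).
#'   \item `ideas_of_reference`, `persecutory` — the two 16-item paranoid
#'     thoughts subscales (beliefs that others observe/talk about oneself,
#'     and that others intend harm), options 1-5, summed; range 16-80.
#'   \item `cohesion` — 6 items, options 1-5, item mean; range 1-5.
#'   \item `conflict_task`, `conflict_relationship` — 3 items each, options
#'     1-5, item mean; range 1-5. Their six items average into the overall
#'     `conflict` index.
#'   \item `performance` — 3 items, options 1-5, item mean; range 1-5.
#' }
#'
#' @param reverse_keys `"ucla"` (standard reverse-keyed UCLA items) or
#'   `"none"` (data already recoded).
#' @return named list of scale definition lists with fields `scale_id`,
#'   `n_items`, `option_range`, `aggregation`, `reverse_keyed`, `score_range`.
#' @export
default_scales <- function(reverse_keys = c("ucla", "none")) {
  reverse_keys <- match.arg(reverse_keys)
  ucla_rev <- if (reverse_keys == "ucla") {
    c(1L, 5L, 6L, 9L, 10L, 15L, 16L, 19L, 20L)
  } else integer(0)
  def <- function(id, k, opt, agg, rev = integer(0)) {
    rng <- if (agg == "sum") k * opt else opt
    list(scale_id = id, n_items = k, option_range = opt, aggregation = agg,
         reverse_keyed = rev, score_range = rng)
  }
  list(
    loneliness = def("loneliness", 20L, c(1L, 4L), "sum", ucla_rev),
    ideas_of_reference = def("ideas_of_reference", 16L, c(1L, 5L), "sum"),
    persecutory = def("persecutory", 16L, c(1L, 5L), "sum"),
    cohesion = def("cohesion", 6L, c(1L, 5L), "mean"),
    conflict_task = def("conflict_task", 3L, c(1L, 5L), "mean"),
    conflict_relationship = def("conflict_relationship", 3L, c(1L, 5L),
                                "mean"),
    performance = def("performance", 3L, c(1L, 5L), "mean")
  )
}

#' Score one person-wave response set on one scale
#'
#' Reverse-keyed items are recoded as `min + max - response` before
#' aggregation. By default a score is computed only from a complete item set;
#' with `impute = TRUE` up to 10\% missing items are replaced by the person's
#' mean over the answered items of that scale.
#'
#' @param responses integer vector of responses indexed by item (length
#'   `n_items`, `NA` for missing), or a long data frame with columns `item`
#'   and `response` for one person/wave/scale.
#' @param definition a scale definition (element of [default_scales()]).
#' @param impute allow person-mean imputation of up to 10\% missing items?
#' @return numeric score, or `NA` if too many items are missing.
#' @export
score_scale <- function(responses, definition, impute = FALSE) {
  if (is.data.frame(responses)) {
    v <- rep(NA_integer_, definition$n_items)
    v[responses$item] <- responses$response
    responses <- v
  }
  if (length(responses) != definition$n_items) {
    stop("expected ", definition$n_items, " items for scale ",
         definition$scale_id, ", got ", length(responses))
  }
  opt <- definition$option_range
  ok <- is.na(responses) | (responses >= opt[1] & responses <= opt[2])
  if (!all(ok)) {
    stop("response out of range [", opt[1], ",", opt[2], "] for scale ",
         definition$scale_id)
  }
  x <- as.numeric(responses)
  rev <- definition$reverse_keyed
  if (length(rev)) x[rev] <- opt[1] + opt[2] - x[rev]
  miss <- is.na(x)
  if (any(miss)) {
    if (!impute || mean(miss) > 0.10 || all(miss)) return(NA_real_)
    x[miss] <- mean(x[!miss])
  }
  s <- if (definition$aggregation == "sum") sum(x) else mean(x)
  rng <- definition$score_range
  if (s < rng[1] - 1e-9 || s > rng[2] + 1e-9) {
    stop("score ", s, " outside declared range for ", definition$scale_id)
  }
  s
}

#' Overall team conflict index
#'
#' The six conflict items (three task, three relationship) are averaged into
#' one index; with equal subscale sizes this equals the mean of the two
#' subscale means.
#'
#' @param task_score,relationship_score subscale item means.
#' @return overall conflict score, `NA` if either input is missing.
#' @export
overall_conflict <- function(task_score, relationship_score) {
  ifelse(is.na(task_score) | is.na(relationship_score), NA_real_,
         (task_score + relationship_score) / 2)
}

#' Score a long-format response table into a person x wave panel
#'
#' Applies [score_scale()] per (person, wave, scale) cell and derives the
#' overall `conflict` index from the two conflict subscales.
#'
#' @param responses long data frame from [read_responses()].
#' @param scales scale definition list (default [default_scales()]).
#' @param impute passed to [score_scale()].
#' @return long panel data frame `person_id`, `wave`, `outcome`, `score`
#'   (missing cells explicit as `NA`).
#' @export
score_panel <- function(responses, scales = default_scales(),
                        impute = FALSE) {
  unknown <- setdiff(unique(responses$scale_id), names(scales))
  if (length(unknown)) {
    stop("responses reference undefined scale(s): ",
         paste(unknown, collapse = ", "))
  }
  cells <- unique(responses[, c("person_id", "wave")])
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    p <- cells$person_id[r]; w <- cells$wave[r]
    sub <- responses[responses$person_id == p & responses$wave == w, ,
                     drop = FALSE]
    sc <- vapply(names(scales), function(s) {
      ss <- sub[sub$scale_id == s, , drop = FALSE]
      if (!nrow(ss)) return(NA_real_)
      score_scale(ss, scales[[s]], impute = impute)
    }, numeric(1))
    out <- c(sc, conflict = overall_conflict(sc[["conflict_task"]],
                                             sc[["conflict_relationship"]]))
    data.frame(person_id = p, wave = w, outcome = names(out),
               score = unname(out), stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  panel <- panel[!is.na(panel$score), , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Cronbach's alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))` with
#' sample (n-1) variances, computed over complete respondents.
#'
#' @param items numeric matrix or data frame, persons in rows, items in
#'   columns, one wave and scale.
#' @return alpha, or `NA` (with a warning) when the total-score variance is
#'   zero.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2L) stop("alpha needs at least 2 items")
  if (nrow(items) < 3L) stop("alpha needs at least 3 complete respondents")
  vt <- stats::var(rowSums(items))
  if (vt == 0) {
    warning("zero total-score variance; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Flag a severe paranoid-thinking score
#'
#' A paranoid-thoughts subscale score strictly exceeding the severity
#' threshold (default 40) is flagged as severe.
#'
#' @param score subscale score.
#' @param scale_id must be `"ideas_of_reference"` or `"persecutory"`.
#' @param threshold severity cut-off (default 40).
#' @return logical.
#' @export
flag_severe <- function(score, scale_id, threshold = 40) {
  if (!scale_id %in% c("ideas_of_reference", "persecutory")) {
    stop("severity flag applies only to the paranoid thoughts subscales")
  }
  score > threshold
}
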