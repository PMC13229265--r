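# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately re-derive each quantity from first
# principles rather than reusing package internals.

# Gini: literal double sum over all ordered pairs.
gini_oracle <- function(w) {
  n <- length(w)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(w[i] - w[j])
  s / (2 * n^2 * mean(w))
}

# One-way within-subject ANOVA by explicit sums of squares on a complete
# persons x waves score matrix.
rm_anova_oracle <- function(mat) {
  n <- nrow(mat); w <- ncol(mat)
  grand <- mean(mat)
  ss_time <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- w * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  ms_time <- ss_time / (w - 1)
  ms_err <- ss_err / ((w - 1) * (n - 1))
  list(F = ms_time / ms_err, df1 = w - 1, df2 = (w - 1) * (n - 1))
}

# Spearman rho as Pearson on average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-sample KS D by exhaustive ECDF sweep over the pooled support.
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(q) mean(a <= q) - mean(b <= q), numeric(1))))
}

# Long panel from a persons x waves score matrix.
panel_from_matrix <- function(mat, outcome = "y",
                              waves = paste0("M", seq_len(ncol(mat)))) {
  persons <- rownames(mat)
  if (is.null(persons)) persons <- paste0("P", seq_len(nrow(mat)))
  data.frame(person_id = rep(persons, ncol(mat)),
             wave = rep(waves, each = nrow(mat)),
             outcome = outcome, score = as.vector(mat),
             stringsAsFactors = FALSE)
}

# Minimal roster: persons in one or two groups plus optional rooms, all
# present over [0, 999].
toy_roster <- function(person_ids, groups = "G1", rooms = character(0),
                       room_category = "shared",
                       first_day = 0L, last_day = 999L) {
  pers <- data.frame(sensor_id = person_ids, kind = "person",
                     group = rep_len(groups, length(person_ids)),
                     room_category = "",
                     first_day = rep_len(first_day, length(person_ids)),
                     last_day = rep_len(last_day, length(person_ids)),
                     stringsAsFactors = FALSE)
  if (length(rooms)) {
    pers <- rbind(pers, data.frame(
      sensor_id = rooms, kind = "room", group = "",
      room_category = rep_len(room_category, length(rooms)),
      first_day = 0L, last_day = 999L, stringsAsFactors = FALSE))
  }
  validate_roster(pers)
}

toy_window <- function(label = "M1", start_day = 0L, end_day = 14L) {
  data.frame(label = label, start_day = start_day, end_day = end_day,
             stringsAsFactors = FALSE)
}
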