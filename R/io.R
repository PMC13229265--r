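# Reading and validating contact streams, sensor rosters, deployment windows
# and questionnaire responses.
#
# Time conventions used throughout the package:
#   * timestamps are integer seconds since the study epoch,
#   * a contact row at time t asserts contact during the half-open interval
#     [t, t + duration),
#   * calendar days are integer day indices since the epoch; day boundaries
#     are placed at a configurable day-start hour (default midnight),
#   * deployment windows are half-open day spans [start_day, end_day),
#   * roster presence windows [first_day, last_day] are inclusive.

#' Convert a timestamp (seconds) to a calendar-day index
#'
#' @param t integer seconds since the study epoch.
#' @param day_start_hour hour (0-23) at which a calendar day begins.
#' @return integer day index since the epoch.
#' @export
contact_day <- function(t, day_start_hour = 0) {
  as.integer(floor((t - day_start_hour * 3600) / 86400))
}

#' Read a contact-interval stream
#'
#' Reads a delimited text file of proximity-contact rows in the SocioPatterns
#' convention: columns `t`, `i`, `j`, one row per active 10-second contact
#' slot between sensors `i` and `j` starting at second `t`. The delimiter
#' (tab or comma) is sniffed from the first line. Pairs are canonicalized so
#' `sensor_a < sensor_b` and rows are returned time-sorted.
#'
#' @param path path to the contacts file.
#' @param resolution temporal resolution in seconds; each row asserts contact
#'   over `[t, t + resolution)`. Default 10 s.
#' @param col_map named character vector mapping the canonical column names
#'   `c(t=, i=, j=)` to the names used in the file header (if it has one).
#' @param roster optional roster data frame (see [read_roster()]); sensor ids
#'   absent from the roster are retained but flagged via the
#'   `"unknown_sensors"` attribute and a warning.
#' @return a data frame with columns `t`, `sensor_a`, `sensor_b`, `duration`.
#' @export
read_contacts <- function(path, resolution = 10,
                          col_map = c(t = "t", i = "i", j = "j"),
                          roster = NULL) {
  stopifnot(length(resolution) == 1L, resolution > 0)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty contacts file: ", path)
    return(empty_contacts())
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- {
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    suppressWarnings(is.na(as.numeric(fields[1])))
  }
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           comment.char = "", quote = "")
  if (has_header) {
    need <- unname(col_map)
    if (!all(need %in% names(raw))) {
      stop("contacts file ", path, " lacks columns: ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    }
    raw <- raw[, need]
  } else {
    if (ncol(raw) < 3L) stop("contacts file needs >= 3 columns: ", path)
    raw <- raw[, 1:3]
  }
  names(raw) <- c("t", "i", "j")

  t_num <- suppressWarnings(as.numeric(raw$t))
  bad <- which(is.na(t_num) | raw$i == "" | raw$j == "")
  if (length(bad)) {
    line <- bad[1] + as.integer(has_header)
    stop("malformed contact row at line ", line, " of ", path)
  }
  if (any(t_num < 0)) {
    line <- which(t_num < 0)[1] + as.integer(has_header)
    stop("negative timestamp at line ", line, " of ", path)
  }
  out <- make_contacts(t_num, raw$i, raw$j, resolution)
  if (!is.null(roster)) {
    ids <- unique(c(out$sensor_a, out$sensor_b))
    unknown <- setdiff(ids, roster$sensor_id)
    attr(out, "unknown_sensors") <- unknown
    if (length(unknown)) {
      warning("contacts reference ", length(unknown),
              " sensor id(s) not in the roster: ",
              paste(unknown, collapse = ", "))
    }
  }
  out
}

empty_contacts <- function() {
  data.frame(t = integer(0), sensor_a = character(0),
             sensor_b = character(0), duration = numeric(0),
             stringsAsFactors = FALSE)
}

#' Build a canonical contact-interval data frame
#'
#' Canonicalizes unordered pairs (`sensor_a < sensor_b`), drops nothing, and
#' sorts by time. Self-contacts are rejected.
#'
#' @param t numeric timestamps (seconds since epoch).
#' @param i,j sensor ids.
#' @param duration interval durations in seconds (scalar or vector).
#' @return contact data frame (`t`, `sensor_a`, `sensor_b`, `duration`).
#' @export
make_contacts <- function(t, i, j, duration = 10) {
  i <- as.character(i); j <- as.character(j)
  if (any(i == j)) stop("self-contact rows are invalid")
  if (any(duration <= 0)) stop("durations must be positive")
  swap <- i > j
  a <- ifelse(swap, j, i)
  b <- ifelse(swap, i, j)
  out <- data.frame(t = as.numeric(t), sensor_a = a, sensor_b = b,
                    duration = rep_len(as.numeric(duration), length(t)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$t, out$sensor_a, out$sensor_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a contact stream to a tab-delimited file
#'
#' Inverse of [read_contacts()]: writes `t i j` rows, one per interval.
#' @param contacts contact data frame.
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(
    data.frame(t = contacts$t, i = contacts$sensor_a, j = contacts$sensor_b),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and validate a sensor roster
#'
#' The roster maps each sensor id either to a person (with a nationality /
#' affiliation `group`) or to a stationary room sensor (with a
#' `room_category` of `"shared"` or `"accommodation"`), together with an
#' inclusive presence window in day indices. Mid-mission crew replacements are
#' expressed naturally: the departing member's `last_day` precedes the
#' incoming member's `first_day`.
#'
#' @param path CSV with header
#'   `sensor_id,kind,group,room_category,first_day,last_day`.
#' @return validated roster data frame with a `"counts"` attribute giving
#'   sensor counts by kind and person counts by group.
#' @export
read_roster <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                       colClasses = "character")
  need <- c("sensor_id", "kind", "group", "room_category",
            "first_day", "last_day")
  if (!all(need %in% names(r))) {
    stop("roster lacks columns: ", paste(setdiff(need, names(r)),
                                         collapse = ", "))
  }
  r <- r[, need]
  r$first_day <- as.integer(r$first_day)
  r$last_day <- as.integer(r$last_day)
  validate_roster(r)
}

#' Validate a roster data frame
#'
#' @param roster data frame with the columns of [read_roster()].
#' @return the roster, with a `"counts"` attribute.
#' @export
validate_roster <- function(roster) {
  if (anyDuplicated(roster$sensor_id)) {
    dup <- roster$sensor_id[duplicated(roster$sensor_id)]
    stop("duplicate sensor id(s) in roster: ", paste(unique(dup),
                                                     collapse = ", "))
  }
  if (!all(roster$kind %in% c("person", "room"))) {
    stop("roster kind must be 'person' or 'room'")
  }
  person <- roster$kind == "person"
  if (any(person & nzchar(roster$room_category))) {
    stop("person sensors must not carry a room_category")
  }
  if (any(person & !nzchar(roster$group))) {
    stop("person sensors must carry a group label")
  }
  if (any(!person & !roster$room_category %in% c("shared", "accommodation"))) {
    stop("room sensors need room_category 'shared' or 'accommodation'")
  }
  if (any(!person & nzchar(roster$group))) {
    stop("room sensors must not carry a group label")
  }
  if (any(roster$last_day < roster$first_day)) {
    stop("roster presence windows must be non-empty (first_day <= last_day)")
  }
  counts <- list(
    kind = table(roster$kind),
    group = table(roster$group[person])
  )
  attr(roster, "counts") <- counts
  roster
}

#' Read deployment-window definitions
#'
#' @param path CSV with header `label,start_day,end_day`; windows are
#'   half-open day spans `[start_day, end_day)`.
#' @return data frame ordered by start day; windows must be pairwise disjoint.
#' @export
read_windows <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("label", "start_day", "end_day")
  if (!all(need %in% names(w))) {
    stop("windows file lacks columns: ", paste(setdiff(need, names(w)),
                                               collapse = ", "))
  }
  w <- w[, need]
  w$start_day <- as.integer(w$start_day)
  w$end_day <- as.integer(w$end_day)
  validate_windows(w)
}

#' Validate deployment windows (disjoint, ordered, non-empty)
#' @param windows data frame with `label`, `start_day`, `end_day`.
#' @return the windows, ordered by start day.
#' @export
validate_windows <- function(windows) {
  if (any(windows$end_day <= windows$start_day)) {
    stop("deployment windows must be non-empty half-open [start, end) spans")
  }
  windows <- windows[order(windows$start_day), , drop = FALSE]
  if (nrow(windows) > 1 &&
      any(windows$start_day[-1] < windows$end_day[-nrow(windows)])) {
    stop("deployment windows must be pairwise disjoint")
  }
  rownames(windows) <- NULL
  windows
}

#' Read long-format questionnaire responses
#'
#' @param path CSV with header `person_id,wave,scale_id,item,response`.
#' @return validated long data frame; `(person, wave, scale, item)` unique.
#' @export
read_responses <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("person_id", "wave", "scale_id", "item", "response")
  if (!all(need %in% names(r))) {
    stop("responses file lacks columns: ", paste(setdiff(need, names(r)),
                                                 collapse = ", "))
  }
  r <- r[, need]
  r$item <- as.integer(r$item)
  r$response <- as.integer(r$response)
  key <- paste(r$person_id, r$wave, r$scale_id, r$item)
  if (anyDuplicated(key)) {
    stop("duplicate (person, wave, scale, item) response rows")
  }
  r
}

#' Restrict a contact stream to one deployment window
#'
#' Keeps intervals whose start time lies within the half-open window
#' `[start_day, end_day)` (in seconds: `[start_day*86400, end_day*86400)`)
#' and whose two sensors are both present on the interval's calendar day per
#' the roster's inclusive presence windows.
#'
#' @param contacts contact data frame from [read_contacts()].
#' @param window single-row window data frame (or a row of
#'   [read_windows()] output).
#' @param roster roster data frame; if `NULL`, presence is not checked.
#' @param day_start_hour day boundary for presence checks.
#' @return filtered contact data frame.
#' @export
filter_window <- function(contacts, window, roster = NULL,
                          day_start_hour = 0) {
  stopifnot(nrow(window) == 1L)
  lo <- window$start_day * 86400
  hi <- window$end_day * 86400
  keep <- contacts$t >= lo & contacts$t < hi
  out <- contacts[keep, , drop = FALSE]
  if (!is.null(roster) && nrow(out)) {
    day <- contact_day(out$t, day_start_hour)
    fa <- roster$first_day[match(out$sensor_a, roster$sensor_id)]
    la <- roster$last_day[match(out$sensor_a, roster$sensor_id)]
    fb <- roster$first_day[match(out$sensor_b, roster$sensor_id)]
    lb <- roster$last_day[match(out$sensor_b, roster$sensor_id)]
    present <- !is.na(fa) & !is.na(fb) &
      day >= fa & day <= la & day >= fb & day <= lb
    out <- out[present, , drop = FALSE]
  }
  if (!nrow(out)) {
    warning("no contacts fall inside window ", window$label)
  }
  rownames(out) <- NULL
  out
}
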