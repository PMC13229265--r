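# Aggregation of contact intervals into per-deployment weighted graphs, and
# the node / group statistics computed from them: strength centrality, Gini
# selectivity of a node's edge weights, daily-strength distributions,
# Kolmogorov-Smirnov comparison of deployments, and group contact matrices.

#' Aggregate window-filtered contacts into a weighted graph
#'
#' Edge weight between two sensors is the total time (seconds) the pair spent
#' in proximity during the window: the sum of the durations of the pair's
#' contact intervals. The graph is undirected with no self-edges.
#'
#' @param contacts contact data frame, already window-filtered
#'   (see [filter_window()]).
#' @param roster roster data frame; used to attach node attributes and to list
#'   sensors present during the window even if they recorded no contact.
#' @param window optional single-row window data frame; when given, nodes are
#'   the sensors whose presence window overlaps it.
#' @param label deployment label stored on the graph.
#' @return object of class `contact_graph`: a list with `edges`
#'   (`sensor_a`, `sensor_b`, `weight` in seconds), `nodes` (roster rows of
#'   all graph nodes) and `label`.
#' @export
aggregate_graph <- function(contacts, roster, window = NULL, label = NULL) {
  key <- paste(contacts$sensor_a, contacts$sensor_b, sep = "\r")
  w <- tapply(contacts$duration, key, sum)
  pairs <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(
    sensor_a = vapply(pairs, `[`, "", 1L),
    sensor_b = vapply(pairs, `[`, "", 2L),
    weight = as.numeric(w),
    stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges <- edges[order(edges$sensor_a, edges$sensor_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- roster
  if (!is.null(window)) {
    stopifnot(nrow(window) == 1L)
    keep <- roster$first_day < window$end_day &
      roster$last_day >= window$start_day
    nodes <- roster[keep, , drop = FALSE]
    if (is.null(label)) label <- window$label
  }
  extra <- setdiff(unique(c(edges$sensor_a, edges$sensor_b)),
                   nodes$sensor_id)
  if (length(extra)) {
    warning("graph contains sensors absent from the node set: ",
            paste(extra, collapse = ", "))
  }
  structure(list(edges = edges, nodes = nodes, label = label),
            class = "contact_graph")
}

#' @exportS3Method base::print
print.contact_graph <- function(x, ...) {
  cat("<contact_graph", if (!is.null(x$label)) paste0(" ", x$label), ">\n",
      sep = "")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%d person, %d room)",
              sum(x$nodes$kind == "person"), sum(x$nodes$kind == "room")),
      "\n")
  cat("  edges:", nrow(x$edges), "| total weight:",
      round(sum(x$edges$weight) / 3600, 2), "h\n")
  invisible(x)
}

#' Strength centrality (weighted degree) in hours
#'
#' The strength of a node is the sum of the weights of all edges incident on
#' it, converted from seconds to hours. Edges to stationary room sensors can
#' be excluded to obtain a purely interpersonal strength.
#'
#' @param graph a `contact_graph`.
#' @param node a sensor id, vector of ids, or `NULL` for all graph nodes.
#' @param include_rooms include edges whose partner is a room sensor?
#' @return named numeric vector of strengths in hours.
#' @export
strength <- function(graph, node = NULL, include_rooms = TRUE) {
  ids <- graph$nodes$sensor_id
  if (is.null(node)) node <- ids
  if (!all(node %in% ids)) {
    stop("unknown node(s): ", paste(setdiff(node, ids), collapse = ", "))
  }
  e <- graph$edges
  if (!include_rooms) {
    rooms <- ids[graph$nodes$kind == "room"]
    e <- e[!(e$sensor_a %in% rooms | e$sensor_b %in% rooms), , drop = FALSE]
  }
  s <- stats::setNames(numeric(length(node)), node)
  if (nrow(e)) {
    inc <- tapply(c(e$weight, e$weight), c(e$sensor_a, e$sensor_b), sum)
    hit <- intersect(node, names(inc))
    s[hit] <- inc[hit]
  }
  s / 3600
}

#' Per-day strength centrality table
#'
#' One row per sensor per calendar day of each deployment window. Days on
#' which a sensor was not present per the roster are marked `present = FALSE`
#' with `strength_h = NA`, distinguishing absence from a present-but-zero
#' contact day.
#'
#' @param contacts contact data frame spanning the deployments.
#' @param roster roster data frame.
#' @param windows deployment windows data frame.
#' @param include_rooms count edges to room sensors in a node's daily
#'   strength?
#' @param day_start_hour day boundary.
#' @return data frame with `sensor_id`, `kind`, `deployment`, `day`,
#'   `present`, `strength_h`.
#' @export
daily_strength <- function(contacts, roster, windows, include_rooms = TRUE,
                           day_start_hour = 0) {
  rooms <- roster$sensor_id[roster$kind == "room"]
  out <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    win <- windows[k, , drop = FALSE]
    cw <- filter_window(contacts, win, roster, day_start_hour)
    if (!include_rooms) {
      cw <- cw[!(cw$sensor_a %in% rooms | cw$sensor_b %in% rooms), ,
               drop = FALSE]
    }
    days <- seq.int(win$start_day, win$end_day - 1L)
    grid <- expand.grid(sensor_id = roster$sensor_id, day = days,
                        stringsAsFactors = FALSE)
    grid$kind <- roster$kind[match(grid$sensor_id, roster$sensor_id)]
    fd <- roster$first_day[match(grid$sensor_id, roster$sensor_id)]
    ld <- roster$last_day[match(grid$sensor_id, roster$sensor_id)]
    grid$present <- grid$day >= fd & grid$day <= ld
    grid$deployment <- win$label
    if (nrow(cw)) {
      d <- contact_day(cw$t, day_start_hour)
      inc <- tapply(c(cw$duration, cw$duration),
                    paste(c(cw$sensor_a, cw$sensor_b), c(d, d), sep = "\r"),
                    sum)
      key <- paste(grid$sensor_id, grid$day, sep = "\r")
      val <- inc[key]
      val[is.na(val)] <- 0
    } else {
      val <- rep(0, nrow(grid))
    }
    grid$strength_h <- as.numeric(val) / 3600
    grid$strength_h[!grid$present] <- NA_real_
    out[[k]] <- grid[, c("sensor_id", "kind", "deployment", "day",
                         "present", "strength_h")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population Gini coefficient of a weight vector
#'
#' `G = sum_{i,j} |w_i - w_j| / (2 n^2 mean(w))` over all ordered pairs. The
#' population (biased) form is used, with no small-sample correction. Returns
#' 0 when all weights are equal and `NA` (flagged missing) when the total
#' weight is zero, where selectivity is undefined.
#'
#' @param w non-negative weight vector (zeros for absent edges included).
#' @return Gini in `[0, 1]`, or `NA_real_` for zero total weight.
#' @export
gini_coef <- function(w) {
  if (any(w < 0)) stop("weights must be non-negative")
  n <- length(w)
  if (n < 2L) stop("Gini needs at least two weights")
  tot <- sum(w)
  if (tot == 0) return(NA_real_)
  ws <- sort(w)
  # sum_{i,j} |w_i - w_j| = 2 * sum_i (2i - n - 1) * w_(i)
  sum_abs <- 2 * sum((2 * seq_len(n) - n - 1) * ws)
  sum_abs / (2 * n^2 * (tot / n))
}

#' Gini selectivity of a node's interaction time
#'
#' Measures how unequally a node's contact time is distributed across its
#' potential partners: high values mean interaction is dominated by one or a
#' few partners, low values mean it is spread evenly. The partner scope is,
#' by default, all *other wearable (person) sensors* in the graph's node set,
#' with zero weights included for partners never contacted; room sensors can
#' be brought into scope with `partner_scope = "all"`.
#'
#' @param graph a `contact_graph`.
#' @param node sensor id(s); `NULL` for all person nodes.
#' @param partner_scope `"persons"` (default) or `"all"`.
#' @return named vector of Gini values (`NA` where the node recorded no
#'   contact time in scope).
#' @export
node_gini <- function(graph, node = NULL,
                      partner_scope = c("persons", "all")) {
  partner_scope <- match.arg(partner_scope)
  ids <- graph$nodes$sensor_id
  persons <- ids[graph$nodes$kind == "person"]
  if (is.null(node)) node <- persons
  if (!all(node %in% ids)) {
    stop("unknown node(s): ", paste(setdiff(node, ids), collapse = ", "))
  }
  scope <- if (partner_scope == "persons") persons else ids
  e <- graph$edges
  vapply(node, function(v) {
    partners <- setdiff(scope, v)
    if (length(partners) < 2L) {
      stop("node ", v, " has fewer than 2 potential partners in scope")
    }
    w <- stats::setNames(numeric(length(partners)), partners)
    hit <- e$sensor_a == v | e$sensor_b == v
    if (any(hit)) {
      other <- ifelse(e$sensor_a[hit] == v, e$sensor_b[hit], e$sensor_a[hit])
      keep <- other %in% partners
      w[other[keep]] <- w[other[keep]] + e$weight[hit][keep]
    }
    gini_coef(unname(w))
  }, numeric(1))
}

#' Empirical CDF of daily strength for one sensor class
#'
#' Right-continuous step function over hours; its value at zero is the
#' zero-contact-day proportion for the class. Absent sensor-days are excluded.
#'
#' @param daily output of [daily_strength()].
#' @param sensor_class `"person"` or `"room"`.
#' @param deployment optional deployment label to restrict to.
#' @return a [stats::ecdf()] function.
#' @export
strength_cdf <- function(daily, sensor_class = c("person", "room"),
                         deployment = NULL) {
  sensor_class <- match.arg(sensor_class)
  x <- class_days(daily, sensor_class, deployment)
  if (!length(x)) stop("no present sensor-days in class ", sensor_class)
  stats::ecdf(x)
}

class_days <- function(daily, sensor_class, deployment = NULL) {
  keep <- daily$kind == sensor_class & daily$present
  if (!is.null(deployment)) keep <- keep & daily$deployment %in% deployment
  daily$strength_h[keep]
}

#' Proportion of present sensor-days with no recorded interaction
#'
#' @inheritParams strength_cdf
#' @return fraction in `[0, 1]`.
#' @export
zero_day_fraction <- function(daily, sensor_class = c("person", "room"),
                              deployment = NULL) {
  sensor_class <- match.arg(sensor_class)
  x <- class_days(daily, sensor_class, deployment)
  if (!length(x)) stop("zero present sensor-days in class ", sensor_class)
  mean(x == 0)
}

#' Two-sample Kolmogorov-Smirnov comparison of daily-strength samples
#'
#' Compares the daily-strength distributions of two deployments (e.g. the
#' first and last) with the two-sample KS test, asymptotic two-sided p-value.
#'
#' @param values_a,values_b numeric samples (daily strengths in hours).
#' @param exact use the exact p-value method (only sensible for small n).
#' @return list with `D` and `p`.
#' @export
compare_deployments_ks <- function(values_a, values_b, exact = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  kt <- suppressWarnings(
    stats::ks.test(values_a, values_b, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Group contact matrix (raw hours and per-pair rescaled)
#'
#' Total person-person contact hours between and within groups, and the same
#' quantities rescaled by the number of possible interacting pairs:
#' `n_g * n_h` off the diagonal and `n_g * (n_g - 1) / 2` on it. Room edges
#' are excluded. Groups of size one get a missing (`NA`) diagonal entry.
#'
#' @param graph a `contact_graph`.
#' @param roster roster (defaults to the graph's node table).
#' @param grouping roster column holding the group label (default `"group"`).
#' @param groups optional subset/order of group labels (e.g. the two
#'   nationality groups, excluding a singleton out-group member).
#' @return list of class `group_contact_matrix` with `raw_hours`, `rescaled`
#'   (symmetric matrices) and `sizes`.
#' @export
group_contact_matrix <- function(graph, roster = graph$nodes,
                                 grouping = "group", groups = NULL) {
  pers <- roster[roster$kind == "person", , drop = FALSE]
  lab <- pers[[grouping]]
  if (any(!nzchar(lab) | is.na(lab))) {
    stop("grouping '", grouping, "' undefined for some person nodes")
  }
  if (is.null(groups)) groups <- sort(unique(lab))
  if (!length(groups) || !all(groups %in% lab)) {
    stop("empty group in grouping '", grouping, "'")
  }
  pers <- pers[lab %in% groups, , drop = FALSE]
  lab <- pers[[grouping]]
  sizes <- stats::setNames(as.integer(table(factor(lab, levels = groups))),
                           groups)
  g <- length(groups)
  raw <- matrix(0, g, g, dimnames = list(groups, groups))
  e <- graph$edges
  ga <- lab[match(e$sensor_a, pers$sensor_id)]
  gb <- lab[match(e$sensor_b, pers$sensor_id)]
  keep <- !is.na(ga) & !is.na(gb)
  for (k in which(keep)) {
    raw[ga[k], gb[k]] <- raw[ga[k], gb[k]] + e$weight[k]
    if (ga[k] != gb[k]) raw[gb[k], ga[k]] <- raw[gb[k], ga[k]] + e$weight[k]
  }
  raw <- raw / 3600
  npairs <- outer(sizes, sizes)
  diag(npairs) <- sizes * (sizes - 1) / 2
  rescaled <- raw / npairs
  rescaled[!is.finite(rescaled)] <- NA_real_
  structure(list(raw_hours = raw, rescaled = rescaled, sizes = sizes),
            class = "group_contact_matrix")
}

#' @exportS3Method base::print
print.group_contact_matrix <- function(x, digits = 3, ...) {
  cat("Group contact matrix (hours)\n")
  print(round(x$raw_hours, digits))
  cat("Rescaled per possible pair (hours/pair)\n")
  print(round(x$rescaled, digits))
  invisible(x)
}

#' Collapse a contact graph to category-level nodes
#'
#' Nodes are grouped by a category (nationality groups, the out-group member,
#' shared rooms, accommodation areas); the weight of a category-pair edge is
#' the sum of all member-pair edge weights, within-category weight becoming a
#' self-loop. Total weight is conserved.
#'
#' @param graph a `contact_graph`.
#' @param category_map named character vector mapping every sensor id in the
#'   graph to a category; defaults to person group labels and room categories
#'   from the node table.
#' @return a `contact_graph` whose nodes are categories (self-loops allowed).
#' @export
grouped_network <- function(graph, category_map = NULL) {
  nodes <- graph$nodes
  if (is.null(category_map)) {
    category_map <- stats::setNames(
      ifelse(nodes$kind == "person", nodes$group, nodes$room_category),
      nodes$sensor_id)
  }
  ids <- unique(c(graph$edges$sensor_a, graph$edges$sensor_b,
                  nodes$sensor_id))
  if (!all(ids %in% names(category_map))) {
    stop("unmapped node(s): ",
         paste(setdiff(ids, names(category_map)), collapse = ", "))
  }
  ca <- category_map[graph$edges$sensor_a]
  cb <- category_map[graph$edges$sensor_b]
  swap <- ca > cb
  tmp <- ca[swap]; ca[swap] <- cb[swap]; cb[swap] <- tmp
  key <- paste(ca, cb, sep = "\r")
  w <- tapply(graph$edges$weight, key, sum)
  pairs <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(
    sensor_a = vapply(pairs, `[`, "", 1L),
    sensor_b = vapply(pairs, `[`, "", 2L),
    weight = as.numeric(w), stringsAsFactors = FALSE)
  cats <- sort(unique(unname(category_map)))
  ndf <- data.frame(sensor_id = cats, kind = "category", group = "",
                    room_category = "", first_day = NA_integer_,
                    last_day = NA_integer_, stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = ndf,
                 label = graph$label), class = "contact_graph")
}
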