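# Synthetic crew generator: contact streams and questionnaire panels with
# known ground truth, emulating a small overwintering crew in two nationality
# groups plus one out-group member, stationary room sensors in shared and
# accommodation spaces, four two-week sensor deployments, room-driven
# gathering (cafeteria and lounge dominant), a tunable nationality-homophily
# schedule, nonwear lapses and two mid-mission crew replacements.
#
# The schedule model is deliberately minimal: each simulated day is a fixed
# sequence of blocks (meals, work, evening); within a block every person
# occupies one room drawn from a block-type-specific multinomial; co-located
# worn pairs emit 10-s contact slots independently with a probability scaled
# by the homophily schedule, and worn persons emit person-room slots with the
# room sensor of the space they occupy. It induces the structures the
# pipeline measures without attempting behavioural realism.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(code)
}

default_windows <- function() {
  data.frame(label = c("M1", "M3", "M6", "M9"),
             start_day = c(0L, 60L, 150L, 240L),
             end_day = c(14L, 74L, 164L, 254L),
             stringsAsFactors = FALSE)
}

# Fixed daily block schedule (seconds from the day's start; sensors are worn
# in the daytime only). Types drive the room-choice multinomial.
default_blocks <- function() {
  data.frame(
    name = c("breakfast", "morning", "lunch", "afternoon", "dinner",
             "evening"),
    type = c("meal", "work", "meal", "work", "meal", "evening"),
    start_s = c(8 * 3600, 8.5 * 3600, 12 * 3600, 13 * 3600, 18 * 3600,
                19.5 * 3600),
    n_slots = c(180L, 1260L, 360L, 1800L, 540L, 900L),
    stringsAsFactors = FALSE)
}

default_rooms <- function() {
  data.frame(
    sensor_id = c("cafeteria", "lounge", "gym", "lab", "workshop",
                  paste0("quarters_", 1:4)),
    category = c(rep("shared", 5), rep("accommodation", 4)),
    stringsAsFactors = FALSE)
}

#' Define a synthetic crew scenario
#'
#' The defaults emulate the study conditions the pipeline targets: a
#' 12-person crew in two nationality groups (6 + 5) plus one out-group
#' member, nine stationary room sensors (five shared rooms, four
#' accommodation areas), four two-week deployments in mission months
#' 1, 3, 6 and 9, a nationality-homophily ratio that increases across
#' deployments, a per-person-day nonwear probability producing zero-contact
#' days, and two members replaced after the first deployment.
#'
#' @param group_sizes named integer vector of nationality-group sizes
#'   (default `c(IT = 6, FR = 5)`); one additional out-group member is
#'   always appended.
#' @param outgroup label of the singleton out-group member
#'   (default `"ESA-MD"`).
#' @param windows deployment windows data frame (`label`, `start_day`,
#'   `end_day`, half-open in days).
#' @param homophily named numeric vector, per deployment label: ratio of the
#'   per-slot contact probability for same-nationality pairs to that of
#'   cross-group pairs.
#' @param activity named numeric vector, per deployment label: multiplier on
#'   the person-person contact probability, letting overall interpersonal
#'   interaction decline across the mission while room usage stays stable.
#' @param nonwear_prob per-person-day probability that a person records
#'   nothing (sensor removed) while still moving through the station.
#' @param contact_prob per-10-s-slot contact probability for a co-located
#'   cross-group pair.
#' @param room_prob per-slot detection probability between a worn person and
#'   the sensor of the room they occupy.
#' @param replacements list of `c(out, in)` sensor-id pairs: `out` leaves
#'   after the first deployment and `in` (same group) arrives at the second.
#'   `NULL` disables replacements; the default replaces the 5th and 8th crew
#'   member, mirroring a two-evacuation mission.
#' @return object of class `crew_scenario`.
#' @export
crew_scenario <- function(group_sizes = c(IT = 6L, FR = 5L),
                          outgroup = "ESA-MD",
                          windows = default_windows(),
                          homophily = c(M1 = 1.2, M3 = 1.5, M6 = 2.0,
                                        M9 = 2.5),
                          activity = c(M1 = 1.0, M3 = 0.85, M6 = 0.70,
                                       M9 = 0.50),
                          nonwear_prob = 0.35,
                          contact_prob = 0.04,
                          room_prob = 0.10,
                          replacements = "default") {
  stopifnot(all(group_sizes >= 1), nonwear_prob >= 0, nonwear_prob <= 1,
            contact_prob > 0, contact_prob <= 1, room_prob >= 0,
            room_prob <= 1)
  windows <- validate_windows(windows)
  if (!all(windows$label %in% names(homophily))) {
    stop("homophily schedule must name every deployment label")
  }
  if (any(homophily <= 0)) stop("homophily ratios must be positive")
  if (!all(windows$label %in% names(activity))) {
    stop("activity schedule must name every deployment label")
  }
  if (any(activity <= 0)) stop("activity multipliers must be positive")
  n <- sum(group_sizes) + 1L
  ids <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("P%02d", seq_len(n))
  groups <- c(rep(names(group_sizes), group_sizes), outgroup)
  if (identical(replacements, "default")) {
    replacements <- if (n >= 9 && nrow(windows) >= 2) {
      list(c(ids[5], intToUtf8(utf8ToInt(ids[n]) + 1L)),
           c(ids[8], intToUtf8(utf8ToInt(ids[n]) + 2L)))
    } else NULL
  }
  structure(list(ids = ids, groups = stats::setNames(groups, ids),
                 group_sizes = group_sizes, outgroup = outgroup,
                 windows = windows, homophily = homophily,
                 activity = activity,
                 nonwear_prob = nonwear_prob, contact_prob = contact_prob,
                 room_prob = room_prob, replacements = replacements,
                 rooms = default_rooms(), blocks = default_blocks()),
            class = "crew_scenario")
}

#' Roster implied by a crew scenario
#'
#' @param scenario a [crew_scenario()].
#' @return validated roster data frame (persons, replacement members and
#'   room sensors, with presence windows).
#' @export
scenario_roster <- function(scenario) {
  w <- scenario$windows
  span <- c(min(w$start_day), max(w$end_day) - 1L)
  ids <- scenario$ids
  groups <- scenario$groups
  first <- stats::setNames(rep(span[1], length(ids)), ids)
  last <- stats::setNames(rep(span[2], length(ids)), ids)
  for (rep_pair in scenario$replacements) {
    out_id <- rep_pair[1]; in_id <- rep_pair[2]
    groups[in_id] <- groups[[out_id]]
    last[out_id] <- w$end_day[1] - 1L
    first[in_id] <- w$start_day[2]
    last[in_id] <- span[2]
  }
  pers <- data.frame(sensor_id = names(groups), kind = "person",
                     group = unname(groups), room_category = "",
                     first_day = unname(first[names(groups)]),
                     last_day = unname(last[names(groups)]),
                     stringsAsFactors = FALSE)
  pers$first_day[is.na(pers$first_day)] <- span[1]
  pers$last_day[is.na(pers$last_day)] <- span[2]
  rooms <- data.frame(sensor_id = scenario$rooms$sensor_id, kind = "room",
                      group = "", room_category = scenario$rooms$category,
                      first_day = span[1], last_day = span[2],
                      stringsAsFactors = FALSE)
  validate_roster(rbind(pers, rooms))
}

# Room-choice probability matrix: persons x rooms, one per block type.
# Meals gather in the cafeteria; work happens mostly in a person's assigned
# work room; evenings gather in the lounge. Quarters are person-specific.
room_prob_matrix <- function(persons, scenario) {
  rooms <- scenario$rooms$sensor_id
  work_rooms <- c("lab", "workshop", "gym")
  quarters <- grep("^quarters_", rooms, value = TRUE)
  np <- length(persons)
  own_quarters <- quarters[(seq_len(np) - 1L) %% length(quarters) + 1L]
  base <- matrix(0, np, length(rooms), dimnames = list(persons, rooms))
  mk <- function(fill) {
    m <- base
    for (k in seq_len(np)) {
      for (nm in names(fill)) {
        if (nm == "work_rooms") {
          m[k, work_rooms] <- m[k, work_rooms] +
            fill[[nm]] / length(work_rooms)
        } else {
          room <- if (nm == "own_quarters") own_quarters[k] else nm
          m[k, room] <- m[k, room] + fill[[nm]]
        }
      }
    }
    m
  }
  # work rooms are drawn anew each block so co-location odds are identical
  # for every pair: any fixed person-to-room assignment would make some
  # pairs structurally more co-located and confound the homophily null
  list(meal = mk(list(cafeteria = 0.90, own_quarters = 0.10)),
       work = mk(list(work_rooms = 0.75, lounge = 0.10, cafeteria = 0.05,
                      own_quarters = 0.10)),
       evening = mk(list(lounge = 0.70, own_quarters = 0.25, gym = 0.05)))
}

#' Simulate a crew contact stream with ground truth
#'
#' Draws, for every present person on every deployment day, a room occupancy
#' per schedule block, then emits 10-s contact slots between co-located worn
#' person pairs (probability `contact_prob`, multiplied by the deployment's
#' homophily ratio for same-nationality pairs) and between worn persons and
#' the sensor of their room (`room_prob`). Nonwear days suppress all of a
#' person's rows while leaving their room occupancy (and hence other people's
#' opportunities) intact.
#'
#' @param scenario a [crew_scenario()].
#' @param seed RNG seed; output is reproducible under a fixed seed.
#' @return list with `contacts` (canonical contact data frame), `roster`,
#'   `windows`, and `truth` — a list carrying the scenario and the expected
#'   per-pair contact hours per deployment (`expected_pair_hours`).
#' @export
simulate_contacts <- function(scenario = crew_scenario(), seed = 1L) {
  roster <- scenario_roster(scenario)
  windows <- scenario$windows
  pers <- roster[roster$kind == "person", , drop = FALSE]
  persons <- pers$sensor_id
  grp <- stats::setNames(pers$group, persons)
  probs <- room_prob_matrix(persons, scenario)
  blocks <- scenario$blocks
  rooms <- scenario$rooms$sensor_id
  q0 <- scenario$contact_prob
  qr <- scenario$room_prob
  pw <- 1 - scenario$nonwear_prob

  acc_t <- list(); acc_a <- list(); acc_b <- list(); acc_n <- 0L
  contacts <- with_seed(seed, {
    for (k in seq_len(nrow(windows))) {
      ratio <- scenario$homophily[[windows$label[k]]]
      act <- scenario$activity[[windows$label[k]]]
      for (day in seq.int(windows$start_day[k], windows$end_day[k] - 1L)) {
        here <- persons[pers$first_day <= day & pers$last_day >= day]
        if (length(here) < 2L) next
        worn <- here[stats::runif(length(here)) < pw]
        av <- character(0); bv <- character(0); cnt <- integer(0)
        bstart <- numeric(0); bslots <- integer(0)
        for (b in seq_len(nrow(blocks))) {
          pm <- probs[[blocks$type[b]]]
          occupancy <- vapply(here, function(p) {
            rooms[sample.int(length(rooms), 1L, prob = pm[p, ])]
          }, character(1))
          ns <- blocks$n_slots[b]
          for (r in unique(occupancy)) {
            occ <- here[occupancy == r]
            occ_w <- intersect(occ, worn)
            if (length(occ_w) >= 2L) {
              prs <- utils::combn(sort(occ_w), 2L)
              q <- act * ifelse(grp[prs[1, ]] == grp[prs[2, ]],
                                q0 * ratio, q0)
              n_hit <- stats::rbinom(ncol(prs), ns, pmin(q, 1))
              keep <- n_hit > 0L
              if (any(keep)) {
                av <- c(av, prs[1, keep]); bv <- c(bv, prs[2, keep])
                cnt <- c(cnt, n_hit[keep])
                bstart <- c(bstart, rep(blocks$start_s[b], sum(keep)))
                bslots <- c(bslots, rep(ns, sum(keep)))
              }
            }
            if (length(occ_w) && qr > 0) {
              n_hit <- stats::rbinom(length(occ_w), ns, qr)
              keep <- n_hit > 0L
              if (any(keep)) {
                av <- c(av, occ_w[keep]); bv <- c(bv, rep(r, sum(keep)))
                cnt <- c(cnt, n_hit[keep])
                bstart <- c(bstart, rep(blocks$start_s[b], sum(keep)))
                bslots <- c(bslots, rep(ns, sum(keep)))
              }
            }
          }
        }
        if (length(cnt)) {
          slots <- unlist(mapply(function(n, m) sample.int(n, m),
                                 bslots, cnt, SIMPLIFY = FALSE),
                          use.names = FALSE)
          acc_n <- acc_n + 1L
          acc_t[[acc_n]] <- day * 86400 + rep(bstart, cnt) + 10 * (slots - 1)
          acc_a[[acc_n]] <- rep(av, cnt)
          acc_b[[acc_n]] <- rep(bv, cnt)
        }
      }
    }
    if (acc_n == 0L) empty_contacts() else {
      make_contacts(unlist(acc_t), unlist(acc_a), unlist(acc_b),
                    duration = 10)
    }
  })
  truth <- list(scenario = scenario, seed = seed,
                expected_pair_hours = expected_pair_hours(scenario))
  list(contacts = contacts, roster = roster, windows = windows,
       truth = truth)
}

#' Expected per-pair contact hours implied by a scenario
#'
#' Closed-form expectation of each person-pair's aggregated contact hours per
#' deployment: per day, the sum over schedule blocks of
#' `n_slots * P(co-located) * q_pair * 10 s`, times the probability both
#' sensors are worn, times the number of days both members are present.
#'
#' @param scenario a [crew_scenario()].
#' @return data frame `deployment`, `sensor_a`, `sensor_b`, `same_group`,
#'   `expected_hours`.
#' @export
expected_pair_hours <- function(scenario) {
  roster <- scenario_roster(scenario)
  pers <- roster[roster$kind == "person", , drop = FALSE]
  persons <- pers$sensor_id
  grp <- stats::setNames(pers$group, persons)
  probs <- room_prob_matrix(persons, scenario)
  blocks <- scenario$blocks
  pw2 <- (1 - scenario$nonwear_prob)^2
  q0 <- scenario$contact_prob
  # co-location probability per block type for every pair
  co <- lapply(probs, function(pm) pm %*% t(pm))
  out <- list()
  for (k in seq_len(nrow(scenario$windows))) {
    w <- scenario$windows[k, ]
    ratio <- scenario$homophily[[w$label]]
    act <- scenario$activity[[w$label]]
    prs <- utils::combn(persons, 2L)
    same <- grp[prs[1, ]] == grp[prs[2, ]]
    sec_day <- numeric(ncol(prs))
    for (b in seq_len(nrow(blocks))) {
      cb <- co[[blocks$type[b]]]
      pco <- cb[cbind(prs[1, ], prs[2, ])]
      q <- act * ifelse(same, pmin(q0 * ratio, 1), q0)
      sec_day <- sec_day + blocks$n_slots[b] * pco * q * 10
    }
    days <- pmax(0, pmin(pers$last_day[match(prs[1, ], persons)],
                         pers$last_day[match(prs[2, ], persons)],
                         w$end_day - 1L) -
                   pmax(pers$first_day[match(prs[1, ], persons)],
                        pers$first_day[match(prs[2, ], persons)],
                        w$start_day) + 1)
    out[[k]] <- data.frame(deployment = w$label, sensor_a = prs[1, ],
                           sensor_b = prs[2, ], same_group = unname(same),
                           expected_hours = sec_day * pw2 * days / 3600,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default generative parameters for the questionnaire outcomes
#'
#' Per-outcome linear growth parameters (score units per wave index):
#' fixed intercept and slope, person-level random-effect SDs and residual SD,
#' with slopes matching the direction and size of change a deteriorating
#' long-isolation mission exhibits (loneliness and paranoid thinking rising,
#' cohesion and performance falling, conflict rising).
#'
#' @return named list of parameter lists (`beta0`, `beta1`, `sd_b0`,
#'   `sd_b1`, `sd_e`, `range`).
#' @export
default_growth_params <- function() {
  prm <- function(b0, b1, s0, s1, se, rng) {
    list(beta0 = b0, beta1 = b1, sd_b0 = s0, sd_b1 = s1, sd_e = se,
         range = rng)
  }
  list(
    loneliness = prm(32, 2.42, 6, 1, 4, c(20, 80)),
    ideas_of_reference = prm(18, 1.35, 4, 0.8, 4, c(16, 80)),
    persecutory = prm(18, 2.35, 5, 1, 4.5, c(16, 80)),
    cohesion = prm(4.0, -0.42, 0.35, 0.08, 0.25, c(1, 5)),
    conflict = prm(1.8, 0.35, 0.30, 0.08, 0.22, c(1, 5)),
    performance = prm(4.2, -0.24, 0.35, 0.08, 0.25, c(1, 5))
  )
}

#' Simulate a scored questionnaire panel with known growth parameters
#'
#' Scores follow the linear growth model
#' `score_pt = (beta0 + b0_p) + (beta1 + b1_p) * t + e_pt` with independent
#' normal person effects and residuals, truncated to the scale's range; `t`
#' is the wave index 0..(waves-1). An optional covariate couples its
#' person-mean-centered deviations into the score (`covariate_coef`), giving
#' synthetic data a known within-person association for validation.
#'
#' @param persons person ids (default the 12-member crew `LETTERS[1:12]`).
#' @param waves wave labels (default `M1, M3, M6, M9`).
#' @param params named list of parameter lists as in
#'   [default_growth_params()]; outcomes generated are `names(params)`.
#' @param seed RNG seed.
#' @param missing optional data frame `person_id`, `wave` of cells to drop
#'   (applied to all outcomes), or with an extra `outcome` column for
#'   outcome-specific masking.
#' @param covariate optional data frame `person_id`, `wave`, `value`.
#' @param covariate_coef coefficient on the covariate's within-person
#'   deviation, recycled over outcomes if named.
#' @return long panel data frame (`person_id`, `wave`, `outcome`, `score`)
#'   with the generative truth in `attr(, "truth")`.
#' @export
simulate_questionnaires <- function(persons = LETTERS[1:12],
                                    waves = c("M1", "M3", "M6", "M9"),
                                    params = default_growth_params(),
                                    seed = 1L, missing = NULL,
                                    covariate = NULL, covariate_coef = 0) {
  np <- length(persons); nw <- length(waves)
  tt <- seq_len(nw) - 1
  cov_dev <- NULL
  if (!is.null(covariate)) {
    cc <- covariate
    mu <- stats::ave(cc$value, cc$person_id, FUN = mean)
    cc$dev <- cc$value - mu
    cov_dev <- cc
  }
  panel <- with_seed(seed, {
    rows <- lapply(names(params), function(oc) {
      pr <- params[[oc]]
      b0 <- pr$beta0 + stats::rnorm(np, 0, pr$sd_b0)
      b1 <- pr$beta1 + stats::rnorm(np, 0, pr$sd_b1)
      sc <- outer(b0, rep(1, nw)) + outer(b1, tt) +
        matrix(stats::rnorm(np * nw, 0, pr$sd_e), np, nw)
      d <- data.frame(person_id = rep(persons, nw),
                      wave = rep(waves, each = np),
                      outcome = oc, score = as.vector(sc),
                      stringsAsFactors = FALSE)
      if (!is.null(cov_dev)) {
        g <- if (length(covariate_coef) > 1) covariate_coef[[oc]] else
          covariate_coef
        if (g != 0) {
          m <- match(paste(d$person_id, d$wave),
                     paste(cov_dev$person_id, cov_dev$wave))
          add <- g * cov_dev$dev[m]
          add[is.na(add)] <- 0
          d$score <- d$score + add
        }
      }
      d$score <- pmin(pmax(d$score, pr$range[1]), pr$range[2])
      d
    })
    do.call(rbind, rows)
  })
  if (!is.null(missing) && nrow(missing)) {
    if ("outcome" %in% names(missing)) {
      drop <- paste(panel$person_id, panel$wave, panel$outcome) %in%
        paste(missing$person_id, missing$wave, missing$outcome)
    } else {
      drop <- paste(panel$person_id, panel$wave) %in%
        paste(missing$person_id, missing$wave)
    }
    panel <- panel[!drop, , drop = FALSE]
  }
  rownames(panel) <- NULL
  attr(panel, "truth") <- list(params = params, seed = seed,
                               covariate_coef = covariate_coef)
  panel
}

#' Expand panel scores into item-level responses with a target alpha
#'
#' For each (person, wave, scale) cell the target score is spread over the
#' scale's items as parallel measurements: every item equals the cell's
#' per-item level plus independent noise whose variance is solved, from the
#' Spearman-Brown relation `rho = alpha / (k - alpha (k - 1))`, so that the
#' expected Cronbach's alpha over persons matches `alpha_target`. Items are
#' rounded and clamped to the scale's option range. The overall `conflict`
#' outcome drives both conflict subscales.
#'
#' @param panel long scored panel (as from [simulate_questionnaires()]).
#' @param scales scale definitions (default [default_scales()] with
#'   `reverse_keys = "none"`: generated responses are already in scored
#'   orientation).
#' @param alpha_target target internal consistency (default 0.9).
#' @param seed RNG seed.
#' @return long response records `person_id`, `wave`, `scale_id`, `item`,
#'   `response`.
#' @export
simulate_items <- function(panel, scales = default_scales("none"),
                           alpha_target = 0.9, seed = 1L) {
  stopifnot(alpha_target > 0, alpha_target < 1)
  src <- c(loneliness = "loneliness",
           ideas_of_reference = "ideas_of_reference",
           persecutory = "persecutory", cohesion = "cohesion",
           conflict_task = "conflict", conflict_relationship = "conflict",
           performance = "performance")
  with_seed(seed, {
    out <- lapply(names(scales), function(sid) {
      def <- scales[[sid]]
      oc <- src[[sid]]
      sub <- panel[panel$outcome == oc, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      k <- def$n_items
      m <- if (def$aggregation == "sum") sub$score / k else sub$score
      rho <- alpha_target / (k - alpha_target * (k - 1))
      v_m <- stats::var(m)
      sd_e <- if (is.na(v_m) || v_m == 0) 0.5 else
        sqrt(v_m * (1 - rho) / rho)
      resp <- round(outer(m, rep(1, k)) +
                      matrix(stats::rnorm(length(m) * k, 0, sd_e),
                             length(m), k))
      resp <- pmin(pmax(resp, def$option_range[1]), def$option_range[2])
      data.frame(person_id = rep(sub$person_id, k),
                 wave = rep(sub$wave, k),
                 scale_id = sid,
                 item = rep(seq_len(k), each = nrow(sub)),
                 response = as.integer(resp),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate the full reference dataset bundle
#'
#' A complete synthetic study: contact stream, roster, deployment windows,
#' item-level questionnaire responses and the generative ground truth, for a
#' 12-member crew with two replacements, nine room sensors and four two-week
#' deployments. The questionnaire missingness mask reproduces the study's
#' sample-size pattern: the two replaced members respond only before/after
#' their hand-over, and one additional missing loneliness wave leaves nine
#' complete cases on that outcome and ten on the team-level outcomes.
#'
#' @param seed RNG seed; the bundle is a deterministic function of it.
#' @return list: `contacts`, `roster`, `windows`, `responses`, `panel`
#'   (scored truth panel), `truth`.
#' @export
make_reference_fixture <- function(seed = 42L) {
  scenario <- crew_scenario()
  sim <- simulate_contacts(scenario, seed = seed)
  roster <- sim$roster
  pers <- roster[roster$kind == "person", , drop = FALSE]
  active <- pers$sensor_id
  waves <- scenario$windows$label
  # replaced members answer only while present
  miss <- list()
  for (rp in scenario$replacements) {
    miss[[length(miss) + 1L]] <- data.frame(person_id = rp[1],
                                            wave = waves[-1])
    miss[[length(miss) + 1L]] <- data.frame(person_id = rp[2],
                                            wave = waves[1])
  }
  miss[[length(miss) + 1L]] <- data.frame(person_id = active[3],
                                          wave = waves[3],
                                          outcome = "loneliness")
  miss <- do.call(rbind, lapply(miss, function(d) {
    if (!"outcome" %in% names(d)) d$outcome <- NA_character_
    d
  }))
  params <- default_growth_params()
  panel_all <- simulate_questionnaires(persons = active, waves = waves,
                                       params = params, seed = seed + 1L)
  gen_mask <- !is.na(miss$outcome)
  drop_all <- paste(panel_all$person_id, panel_all$wave) %in%
    paste(miss$person_id[!gen_mask], miss$wave[!gen_mask])
  drop_oc <- paste(panel_all$person_id, panel_all$wave, panel_all$outcome) %in%
    paste(miss$person_id[gen_mask], miss$wave[gen_mask],
          miss$outcome[gen_mask])
  panel <- panel_all[!(drop_all | drop_oc), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "truth") <- attr(panel_all, "truth")
  responses <- simulate_items(panel, seed = seed + 2L)
  list(contacts = sim$contacts, roster = roster, windows = sim$windows,
       responses = responses, panel = panel,
       truth = c(sim$truth, list(growth_params = params)))
}

#' Write a dataset bundle to delimited text files
#'
#' Writes `contacts.tsv`, `roster.csv`, `windows.csv`, `responses.csv` and
#' `truth.json` under `dir`.
#'
#' @param bundle output of [make_reference_fixture()] or
#'   [simulate_contacts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contacts(bundle$contacts, file.path(dir, "contacts.tsv"))
  utils::write.csv(bundle$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$windows, file.path(dir, "windows.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$responses)) {
    utils::write.csv(bundle$responses, file.path(dir, "responses.csv"),
                     row.names = FALSE)
  }
  truth <- bundle$truth
  truth$scenario <- truth$scenario[setdiff(names(truth$scenario),
                                           c("blocks", "rooms"))]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
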