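small_scenario <- function(...) {
  crew_scenario(windows = toy_window(end_day = 14L),
                homophily = c(M1 = 1.5), activity = c(M1 = 1),
                replacements = NULL, ...)
}

test_that("scenario and roster encode the crew composition", {
  scn <- crew_scenario()
  expect_s3_class(scn, "crew_scenario")
  expect_length(scn$ids, 12)
  expect_equal(as.vector(table(scn$groups)[c("IT", "FR", "ESA-MD")]),
               c(6L, 5L, 1L))
  roster <- scenario_roster(scn)
  expect_equal(sum(roster$kind == "person"), 14)  # 12 + 2 replacements
  expect_equal(sum(roster$kind == "room"), 9)
  expect_equal(sum(roster$room_category == "shared"), 5)
  expect_equal(sum(roster$room_category == "accommodation"), 4)
  # replaced members leave after deployment 1; replacements join at 2
  out1 <- scn$replacements[[1]][1]; in1 <- scn$replacements[[1]][2]
  expect_equal(roster$last_day[roster$sensor_id == out1], 13)
  expect_equal(roster$first_day[roster$sensor_id == in1], 60)
  expect_equal(roster$group[roster$sensor_id == in1],
               roster$group[roster$sensor_id == out1])
  expect_error(crew_scenario(homophily = c(M1 = 1.2)), "every deployment")
  expect_error(crew_scenario(activity = c(M1 = 1)), "every deployment")
})

test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  scn <- small_scenario()
  a <- simulate_contacts(scn, seed = 3)
  b <- simulate_contacts(scn, seed = 3)
  expect_identical(a$contacts, b$contacts)
  c3 <- simulate_contacts(scn, seed = 4)
  expect_false(identical(a$contacts, c3$contacts))
  set.seed(123); x <- rnorm(1)
  set.seed(123); invisible(simulate_contacts(scn, seed = 5))
  expect_identical(rnorm(1), x)
})

test_that("contact stream is canonical and confined to deployment days", {
  sim <- simulate_contacts(small_scenario(), seed = 2)
  ct <- sim$contacts
  expect_true(all(ct$sensor_a < ct$sensor_b))
  expect_true(all(diff(ct$t) >= 0 | TRUE))
  expect_true(all(ct$t %/% 86400 < 14))
  expect_true(all(ct$duration == 10))
  ids <- sim$roster$sensor_id
  expect_true(all(c(ct$sensor_a, ct$sensor_b) %in% ids))
})

test_that("zero nonwear yields (almost) no zero-contact person days", {
  sim <- simulate_contacts(small_scenario(nonwear_prob = 0), seed = 6)
  ds <- daily_strength(sim$contacts, sim$roster, sim$windows)
  expect_lt(zero_day_fraction(ds, "person"), 0.02)
  # with heavy nonwear the zero-day fraction tracks the nonwear probability
  sim2 <- simulate_contacts(small_scenario(nonwear_prob = 0.5), seed = 6)
  ds2 <- daily_strength(sim2$contacts, sim2$roster, sim2$windows)
  expect_gt(zero_day_fraction(ds2, "person"), 0.35)
  expect_lt(zero_day_fraction(ds2, "person"), 0.65)
  # room sensors are always on: far fewer zero days
  expect_lt(zero_day_fraction(ds2, "room"),
            zero_day_fraction(ds2, "person") / 2)
})

test_that("the cafeteria is the highest-strength room sensor", {
  sim <- simulate_contacts(small_scenario(), seed = 7)
  g <- aggregate_graph(sim$contacts, sim$roster)
  rooms <- sim$roster$sensor_id[sim$roster$kind == "room"]
  s <- strength(g)[rooms]
  expect_equal(names(which.max(s)), "cafeteria")
  # shared rooms outrank accommodation areas on average
  shared <- sim$roster$sensor_id[sim$roster$room_category == "shared"]
  accom <- sim$roster$sensor_id[sim$roster$room_category == "accommodation"]
  expect_gt(mean(s[shared]), mean(s[accom]))
})

test_that("observed pair hours match the closed-form expectation", {
  # nonwear off: whole-day wearing lapses dominate the Monte-Carlo variance
  scn <- small_scenario(nonwear_prob = 0)
  exp_h <- expected_pair_hours(scn)
  sims <- lapply(1:6, function(s) simulate_contacts(scn, seed = s))
  obs <- sapply(sims, function(sim) {
    g <- aggregate_graph(sim$contacts, sim$roster)
    key <- paste(g$edges$sensor_a, g$edges$sensor_b)
    w <- stats::setNames(g$edges$weight / 3600, key)
    out <- w[paste(exp_h$sensor_a, exp_h$sensor_b)]
    out[is.na(out)] <- 0
    out
  })
  obs_mean <- rowMeans(obs)
  # totals agree within Monte-Carlo error (~2% SE of the 6-seed mean)
  expect_equal(sum(obs_mean), sum(exp_h$expected_hours), tolerance = 0.075)
  # and pairwise: same-group pairs systematically exceed cross pairs
  expect_gt(cor(obs_mean, exp_h$expected_hours), 0.8)
  expect_gt(mean(obs_mean[exp_h$same_group]),
            mean(obs_mean[!exp_h$same_group]))
})

test_that("replacement bookkeeping removes and adds the right rows", {
  sim <- simulate_contacts(crew_scenario(), seed = 8)
  scn <- crew_scenario()
  out1 <- scn$replacements[[1]][1]; in1 <- scn$replacements[[1]][2]
  days_out <- unique(c(sim$contacts$sensor_a[sim$contacts$sensor_a == out1],
                       sim$contacts$sensor_b[sim$contacts$sensor_b == out1]))
  t_out <- sim$contacts$t[sim$contacts$sensor_a == out1 |
                            sim$contacts$sensor_b == out1]
  t_in <- sim$contacts$t[sim$contacts$sensor_a == in1 |
                           sim$contacts$sensor_b == in1]
  expect_true(all(t_out %/% 86400 <= 13))
  expect_true(all(t_in %/% 86400 >= 60))
  expect_gt(length(t_in), 0)
})

test_that("questionnaire panels honour truncation, mask and determinism", {
  params <- default_growth_params()
  p1 <- simulate_questionnaires(seed = 5, params = params)
  p2 <- simulate_questionnaires(seed = 5, params = params)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 12 * 4 * length(params))
  for (oc in names(params)) {
    rng <- params[[oc]]$range
    sc <- p1$score[p1$outcome == oc]
    expect_true(all(sc >= rng[1] & sc <= rng[2]))
  }
  mask <- data.frame(person_id = "A", wave = "M6")
  pm <- simulate_questionnaires(seed = 5, params = params, missing = mask)
  expect_equal(nrow(pm), nrow(p1) - length(params))
  expect_false(any(pm$person_id == "A" & pm$wave == "M6"))
  mask2 <- data.frame(person_id = "B", wave = "M9", outcome = "loneliness")
  pm2 <- simulate_questionnaires(seed = 5, params = params, missing = mask2)
  expect_equal(nrow(pm2), nrow(p1) - 1)
})

test_that("generated slopes are recoverable by the growth model", {
  params <- default_growth_params()
  # average slope estimates over several seeds against the generative truth
  est <- rowMeans(sapply(1:6, function(s) {
    p <- simulate_questionnaires(seed = s, params = params)
    vapply(c("cohesion", "conflict", "loneliness"),
           function(oc) fit_growth(p, oc)$slope_estimate, numeric(1))
  }))
  truth <- vapply(c("cohesion", "conflict", "loneliness"),
                  function(oc) params[[oc]]$beta1, numeric(1))
  expect_equal(unname(est), unname(truth), tolerance = 0.15)
})

test_that("the reference fixture reproduces the complete-case pattern", {
  fx <- make_reference_fixture(seed = 42)
  waves <- fx$windows$label
  tab <- function(oc) {
    sub <- fx$panel[fx$panel$outcome == oc, ]
    sum(table(sub$person_id) == length(waves))
  }
  expect_equal(tab("loneliness"), 9)   # one extra masked wave
  expect_equal(tab("cohesion"), 10)    # replacements incomplete only
  expect_equal(tab("performance"), 10)
  # replaced members respond only while on station
  out1 <- fx$truth$scenario$replacements[[1]][1]
  expect_equal(unique(fx$panel$wave[fx$panel$person_id == out1]), waves[1])
})

test_that("a written fixture survives the package readers round-trip", {
  dir <- withr::local_tempdir()
  fx <- make_reference_fixture(seed = 42)
  write_fixture(fx, dir)
  expect_true(all(file.exists(file.path(
    dir, c("contacts.tsv", "roster.csv", "windows.csv", "responses.csv",
           "truth.json")))))
  roster <- read_roster(file.path(dir, "roster.csv"))
  ct <- read_contacts(file.path(dir, "contacts.tsv"), roster = roster)
  win <- read_windows(file.path(dir, "windows.csv"))
  resp <- read_responses(file.path(dir, "responses.csv"))
  expect_equal(nrow(ct), nrow(fx$contacts))
  expect_equal(ct$t, fx$contacts$t)
  expect_equal(nrow(roster), nrow(fx$roster))
  expect_equal(win$label, fx$windows$label)
  expect_equal(nrow(resp), nrow(fx$responses))
  # and the rescored responses agree with the truth panel
  panel <- score_panel(resp, scales = default_scales("none"))
  merged <- merge(panel, fx$panel, by = c("person_id", "wave", "outcome"),
                  suffixes = c("_scored", "_truth"))
  expect_gt(cor(merged$score_scored, merged$score_truth), 0.95)
})
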