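cfg <- analysis_config()

test_that("midpoint conventions give the worked-example episode", {
  ep <- classify_episodes(worked_example_fixture(), cfg)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset_age_days, 55)
  expect_equal(ep$recovery_age_days, 85)
  expect_equal(ep$duration_days, 30)   # (70-40)/2 + (100-70)/2
  expect_equal(ep$onset_kind, "interval")
  expect_false(ep$censored)
})

test_that("series never below the cutoff yield no episodes", {
  m <- generate_fixture(data.frame(child_id = "k", age_days = c(10, 40, 70),
                                   wlz = c(-1, -1.9, 0)))
  expect_equal(nrow(classify_episodes(m, cfg)), 0)
  m2 <- generate_fixture(data.frame(child_id = "k", age_days = c(10, 40),
                                    wlz = c(NA, NA), laz = c(-1, -1)))
  expect_equal(nrow(classify_episodes(m2, cfg)), 0)
})

test_that("a dip above the cutoff shorter than the washout continues the episode", {
  m <- generate_fixture(data.frame(
    child_id = "k",
    age_days = c(60, 90, 120, 150, 180, 210, 240),
    wlz = c(-2.5, -2.5, -1, -2.5, -1, -1, -1)))
  ep <- classify_episodes(m, cfg)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset_kind, "at_enrollment")
  expect_equal(ep$onset_age_days, 30)  # halfway between birth and first visit
  expect_equal(ep$recovery_age_days, 165)
  # with a 30-day washout the same data split into two episodes
  ep30 <- classify_episodes(m, analysis_config(washout_days = 30))
  expect_equal(nrow(ep30), 2)
})

test_that("onset kinds follow the enrollment conventions", {
  born <- generate_fixture(data.frame(child_id = "b", age_days = c(2, 32, 62, 122),
                                      wlz = c(-2.5, -1, -1, -1)))
  ep <- classify_episodes(born, cfg)
  expect_equal(ep$onset_kind, "at_birth")
  expect_equal(ep$onset_age_days, 2)   # the birth measure's age, not 0
  expect_true(ep$born_wasted)

  late <- generate_fixture(data.frame(child_id = "l", age_days = c(100, 130, 160, 220),
                                      wlz = c(-2.5, -1, -1, -1)))
  ep2 <- classify_episodes(late, cfg)
  expect_equal(ep2$onset_kind, "at_enrollment")
  expect_equal(ep2$onset_age_days, 50)
  expect_false(ep2$born_wasted)
})

test_that("children wasted at the last measurement are censored there", {
  m <- generate_fixture(data.frame(child_id = "k", age_days = c(10, 40, 70),
                                   wlz = c(-1, -1, -2.5)))
  ep <- classify_episodes(m, cfg)
  expect_true(ep$censored)
  expect_true(is.na(ep$recovery_age_days))
  expect_true(is.na(ep$duration_days))
  expect_equal(ep$last_obs_age_days, 70)
})

test_that("the two-measurement recovery variant demands a confirming visit", {
  m <- generate_fixture(data.frame(child_id = "k", age_days = c(40, 70, 100),
                                   wlz = c(-1.5, -2.5, -1.5)))
  ep_span <- classify_episodes(m, cfg)
  expect_false(ep_span$censored)     # trailing above spell accepted
  ep_two <- classify_episodes(m, analysis_config(recovery_rule = "two_measurements"))
  expect_true(ep_two$censored)       # single confirming measurement is not enough
  ep_two2 <- classify_episodes(worked_example_fixture(),
                               analysis_config(recovery_rule = "two_measurements"))
  expect_false(ep_two2$censored)
})

test_that("classifier matches the brute-force day-grid oracle on random series", {
  set.seed(20240917)
  n_series <- 120
  for (i in seq_len(n_series)) {
    s <- random_series()
    m <- generate_fixture(data.frame(child_id = "k", age_days = s$age_days,
                                     wlz = s$wlz))
    for (washout in c(30, 60, 90)) {
      for (cutoff in c(-2, -3)) {
        cfg_i <- analysis_config(washout_days = washout)
        cond <- if (cutoff == -2) "wasting" else "severe_wasting"
        got <- classify_episodes(m, cfg_i, condition = cond)
        want <- oracle_episodes(s$age_days, s$wlz, cutoff, washout)
        expect_episodes_equal(got, want,
                              info = sprintf("series %d washout %d cutoff %g",
                                             i, washout, cutoff))
      }
    }
  }
})

test_that("severe-wasting episodes lie inside wasting sub-threshold spans", {
  set.seed(99)
  for (i in 1:100) {
    s <- random_series()
    m <- generate_fixture(data.frame(child_id = "k", age_days = s$age_days,
                                     wlz = s$wlz))
    ws <- classify_episodes(m, cfg, "wasting")
    sv <- classify_episodes(m, cfg, "severe_wasting")
    if (!nrow(sv)) next
    # every severe onset falls within some wasting episode's [onset, end]
    for (j in seq_len(nrow(sv))) {
      ends <- ifelse(ws$censored, ws$last_obs_age_days, ws$recovery_age_days)
      expect_true(any(sv$onset_age_days[j] >= ws$onset_age_days - 1e-9 &
                        sv$onset_age_days[j] <= ends + 1e-9),
                  info = sprintf("series %d severe episode %d", i, j))
    }
  }
})

test_that("person-time at risk respects onset, recovery and washout", {
  m <- worked_example_fixture()
  ep <- classify_episodes(m, cfg)
  ri <- person_time_at_risk(m, ep, cfg)
  at_risk <- ri[ri$at_risk, ]
  expect_equal(sum(at_risk$end_age_days - at_risk$start_age_days), 15)

  # no episodes: entire span at risk
  m0 <- generate_fixture(data.frame(child_id = "k", age_days = c(0, 720),
                                    wlz = c(-1, -1)))
  ri0 <- person_time_at_risk(m0, classify_episodes(m0, cfg), cfg)
  expect_equal(ri0$at_risk, TRUE)
  expect_equal(ri0$end_age_days - ri0$start_age_days, 720)

  # censored episode removes all time through series end
  mc <- generate_fixture(data.frame(child_id = "k",
                                    age_days = c(400, 470, 500, 530, 720),
                                    wlz = c(-1, -1, -2.6, -2.4, -2.2)))
  epc <- classify_episodes(mc, cfg)
  expect_true(epc$censored)
  ric <- person_time_at_risk(mc, epc, cfg)
  expect_equal(max(ric$end_age_days[ric$at_risk]), epc$onset_age_days)
})

test_that("at-risk plus not-at-risk days equal the observed span exactly", {
  set.seed(7)
  for (i in 1:100) {
    s <- random_series()
    if (all(is.na(s$wlz))) next
    m <- generate_fixture(data.frame(child_id = "k", age_days = s$age_days,
                                     wlz = s$wlz))
    for (washout in c(30, 60, 90)) {
      cfg_i <- analysis_config(washout_days = washout)
      ep <- classify_episodes(m, cfg_i)
      ri <- person_time_at_risk(m, ep, cfg_i)
      span <- diff(range(s$age_days[!is.na(s$wlz)]))
      expect_equal(sum(ri$end_age_days - ri$start_age_days), span,
                   info = sprintf("series %d washout %d", i, washout))
      expect_true(all(ri$end_age_days > ri$start_age_days))
      # intervals are non-overlapping and ordered
      expect_true(all(diff(ri$start_age_days) >= 0))
      expect_true(all(utils::head(ri$end_age_days, -1) <=
                        utils::tail(ri$start_age_days, -1) + 1e-9))
    }
  }
})

test_that("episode counts are monotone non-increasing in washout length", {
  set.seed(123)
  for (i in 1:80) {
    s <- random_series()
    m <- generate_fixture(data.frame(child_id = "k", age_days = s$age_days,
                                     wlz = s$wlz))
    counts <- vapply(c(30, 60, 90), function(w) {
      nrow(classify_episodes(m, analysis_config(washout_days = w)))
    }, numeric(1))
    expect_true(counts[1] >= counts[2] && counts[2] >= counts[3],
                info = sprintf("series %d: %s", i,
                               paste(counts, collapse = "/")))
  }
})

test_that("incidence rate is onsets per 1,000 at-risk days with Poisson CI", {
  ep <- tibble::tibble(cohort_id = "c1", child_id = as.character(1:2),
                       episode_id = 1L, condition = "wasting",
                       onset_age_days = c(100, 200), onset_kind = "interval",
                       recovery_age_days = c(150, 250), censored = FALSE,
                       duration_days = 50, born_wasted = FALSE,
                       first_obs_age_days = 0, last_obs_age_days = 720)
  ri <- tibble::tibble(cohort_id = "c1", child_id = as.character(1:4),
                       start_age_days = 0, end_age_days = 1000,
                       at_risk = TRUE)
  r <- incidence_rate(ep, ri, c(0, 1000))
  expect_equal(r$rate, 0.5)  # 2 onsets / 4000 days * 1000
  # no onsets: rate zero, upper CI above zero
  r0 <- incidence_rate(ep[0, ], ri, c(0, 1000))
  expect_equal(r0$rate, 0)
  expect_gt(r0$ci_hi, 0)
  # zero person-time flagged undefined
  rz <- incidence_rate(ep, ri[0, ], c(0, 1000))
  expect_true(rz$undefined)
})

test_that("estimated rate recovers a constant simulated hazard", {
  # direct hazard simulation, independent of the z-score generator: onsets
  # arrive at rate h while at risk, each episode lasts 40 days below the
  # cutoff, and measurements are taken every 5 days so midpoint error is
  # small relative to Monte-Carlo noise
  set.seed(31)
  h <- 0.002
  n_children <- 150
  horizon <- 720
  episode_len <- 40
  washout <- 60
  rows <- list()
  true_onsets <- 0
  true_at_risk <- 0
  for (i in seq_len(n_children)) {
    status <- rep(FALSE, horizon + 1)   # wasted?
    t <- 0
    while (t <= horizon) {
      gap <- rgeom(1, h) + 1
      onset <- t + gap
      if (onset > horizon) { true_at_risk <- true_at_risk + (horizon - t); break }
      true_at_risk <- true_at_risk + gap
      true_onsets <- true_onsets + 1
      status[onset:min(onset + episode_len - 1, horizon) + 1] <- TRUE
      t <- onset + episode_len + washout
    }
    ages <- seq(0, horizon, by = 5)
    rows[[i]] <- data.frame(child_id = sprintf("c%03d", i), age_days = ages,
                            wlz = ifelse(status[ages + 1], -2.5, -1))
  }
  m <- generate_fixture(do.call(rbind, rows))
  ep <- classify_episodes(m, analysis_config())
  ri <- person_time_at_risk(m, ep, analysis_config())
  r <- incidence_rate(ep, ri, c(0, horizon))
  mc_se <- 1000 * sqrt(true_onsets) / true_at_risk
  expect_lt(abs(r$rate - 1000 * true_onsets / true_at_risk), 3 * mc_se)
  expect_lt(abs(r$rate - 1000 * h) / (1000 * h), 0.25)
})

test_that("recovery proportions count horizons correctly and monotonically", {
  ep <- tibble::tibble(
    cohort_id = "c1", child_id = sprintf("k%d", 1:4), episode_id = 1L,
    condition = "wasting",
    onset_age_days = 100, onset_kind = "interval",
    recovery_age_days = c(120, 145, 180, NA),
    censored = c(FALSE, FALSE, FALSE, TRUE),
    duration_days = c(20, 45, 80, NA), born_wasted = FALSE,
    first_obs_age_days = 0, last_obs_age_days = 400)
  rp <- recovery_proportions(ep, c(30, 60, 90), denominator = "all")
  expect_equal(rp$proportion, c(0.25, 0.50, 0.75))
  # saturation: all recovered within the shortest horizon
  ep2 <- ep[1:3, ]; ep2$duration_days <- c(10, 20, 25)
  ep2$recovery_age_days <- 100 + ep2$duration_days
  rp2 <- recovery_proportions(ep2, c(30, 60, 90))
  expect_equal(rp2$proportion, c(1, 1, 1))
  # horizon order in the call does not matter
  rp3 <- recovery_proportions(ep, c(90, 30, 60), denominator = "all")
  expect_equal(rp3, rp)
  # monotone in horizon under both denominator rules, on random episode sets
  set.seed(5)
  for (i in 1:40) {
    s <- random_series()
    m <- generate_fixture(data.frame(child_id = "k", age_days = s$age_days,
                                     wlz = s$wlz))
    ep_i <- classify_episodes(m, cfg)
    if (!nrow(ep_i)) next
    for (den in c("sufficient_followup", "all")) {
      p <- recovery_proportions(ep_i, c(30, 60, 90), denominator = den)$proportion
      p <- p[!is.na(p)]
      expect_true(all(diff(p) >= -1e-12), info = paste("series", i, den))
    }
  }
})

test_that("short-follow-up censored episodes leave the default denominator", {
  ep <- tibble::tibble(
    cohort_id = "c1", child_id = c("a", "b"), episode_id = 1L,
    condition = "wasting", onset_age_days = c(100, 380),
    onset_kind = "interval", recovery_age_days = c(125, NA),
    censored = c(FALSE, TRUE), duration_days = c(25, NA),
    born_wasted = FALSE, first_obs_age_days = 0,
    last_obs_age_days = c(400, 400))
  rp <- recovery_proportions(ep, 90)
  # censored episode observed only 20 days: excluded from the 90-day horizon
  expect_equal(rp$n_denominator, 1)
  expect_equal(rp$proportion, 1)
  rp_all <- recovery_proportions(ep, 90, denominator = "all")
  expect_equal(rp_all$proportion, 0.5)
})

test_that("median duration obeys the censoring rule", {
  ep <- tibble::tibble(
    cohort_id = "c1", child_id = sprintf("k%d", 1:3), episode_id = 1L,
    condition = "wasting", onset_age_days = 0, onset_kind = "interval",
    recovery_age_days = c(30, 42, 60), censored = FALSE,
    duration_days = c(30, 42, 60), born_wasted = FALSE,
    first_obs_age_days = 0, last_obs_age_days = 700)
  expect_equal(median_duration(ep)$median_duration_days, 42)
  # exactly half censored: undefined (rule is strictly less than half)
  ep2 <- dplyr::bind_rows(ep, dplyr::mutate(ep, child_id = paste0(child_id, "x"),
                                            censored = TRUE,
                                            recovery_age_days = NA,
                                            duration_days = NA))
  md <- median_duration(ep2)
  expect_false(md$defined)
  expect_true(is.na(md$median_duration_days))
  expect_equal(median_duration(ep[2, ])$median_duration_days, 42)
})
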