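test_that("onset days cover calendar arithmetic and the exclusion reasons", {
  od <- onset_days(c("20200410", "202004", "20200401", "20200301",
                     "20201332", "20200405"),
                   c("20200405", "20200405", "20200405", "20200228",
                     "20200401", "20200405"))
  expect_equal(od$days, c(5L, NA, NA, 2L, NA, 0L))
  expect_equal(od$reason, c(NA, "partial_date", "negative_interval",
                            NA, "invalid_date", NA))
  # accounting: every record is included or excluded with a reason
  expect_equal(sum(!is.na(od$days)) + sum(!is.na(od$reason)), nrow(od))
})

test_that("summary reports sample SD and a proper cumulative curve", {
  s <- onset_summary(c(0L, 5L, 10L))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 5)
  expect_equal(s$curve$cumulative_proportion[s$curve$day == 10], 1)
  expect_true(all(diff(s$curve$cumulative_proportion) >= 0))
  s1 <- onset_summary(7L)
  expect_true(is.na(s1$sd))
  expect_equal(s1$n, 1L)
  s0 <- onset_summary(integer(0))
  expect_equal(s0$n, 0L)
})

test_that("planted exponential onset means are recovered through the pipeline", {
  cfg <- scenario_config(1200, 1200, true_or = 1, baseline_event_prob = 0.5,
                         confounders = no_confounding(),
                         onset_dist = list(name = "exponential",
                                           mean_exposed = 5,
                                           mean_control = 5),
                         seed = 41)
  scn <- generate_scenario(cfg)
  cohort <- run_pipeline(scn$tables, bundled_smq("covid19"),
                         bundled_smq("aki"))
  ob <- onset_by_group(cohort)
  for (g in c("remdesivir", "control")) {
    s <- ob[[g]]
    expect_gt(s$n, 100)
    expect_lt(abs(s$mean - 5), 3 * s$sd / sqrt(s$n))
    # included + excluded covers every event case of the group
    n_events <- sum(cohort$event & cohort$exposure == g)
    expect_equal(s$n + sum(s$excluded), n_events)
  }
})

test_that("date-quality exclusions match the generator's bookkeeping", {
  cfg <- scenario_config(600, 600, true_or = 1, baseline_event_prob = 0.4,
                         confounders = no_confounding(),
                         partial_date_prob = 0.3,
                         negative_interval_prob = 0.1, seed = 42)
  scn <- generate_scenario(cfg)
  cohort <- run_pipeline(scn$tables, bundled_smq("covid19"),
                         bundled_smq("aki"))
  ob <- onset_by_group(cohort)
  truth <- scn$truth$cases
  n_obs <- sum(truth$onset_observable)
  expect_equal(ob$remdesivir$n + ob$control$n, n_obs)
  # the included onset days are exactly the planted ones
  m <- match(cohort$caseid, truth$caseid)
  od <- onset_days(cohort$event_dt, cohort$start_dt)
  inc <- cohort$event & !is.na(od$days)
  expect_equal(od$days[inc], truth$onset_days[m][inc])
})

test_that("outcome comparison recovers a planted death probability", {
  set.seed(43)
  n_aki <- 500; n_non <- 1500
  cohort <- data.frame(
    caseid = as.character(1:(n_aki + n_non)),
    exposure = "remdesivir",
    event = rep(c(TRUE, FALSE), c(n_aki, n_non)),
    outcome = c(ifelse(runif(n_aki) < 0.3, "DE", "HO"),
                ifelse(runif(n_non) < 0.15, "DE", "HO")),
    stringsAsFactors = FALSE)
  oc <- outcome_comparison(cohort, "remdesivir")
  p_hat <- oc$pct_event[oc$outcome == "DE"] / 100
  expect_lt(abs(p_hat - 0.3), 1.96 * sqrt(0.3 * 0.7 / n_aki))
  # column percentages over outcome categories sum to 100
  expect_equal(sum(oc$pct_event), 100)
  expect_equal(sum(oc$pct_nonevent), 100)
  expect_true(all(oc$test %in% c("chi-square", "fisher")))
})

test_that("a group with no outcome rows yields zero counts and no tests", {
  cohort <- data.frame(caseid = c("1", "2"), exposure = "control",
                       event = c(TRUE, FALSE), outcome = "none",
                       stringsAsFactors = FALSE)
  oc <- outcome_comparison(cohort, "control")
  expect_true(all(oc$n_event == 0))
  expect_true(all(is.na(oc$p)))
})
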