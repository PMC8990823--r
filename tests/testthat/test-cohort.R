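covid_q <- bundled_smq("covid19", "narrow")
aki_n <- bundled_smq("aki", "narrow")
aki_b <- bundled_smq("aki", "broad")

test_that("exposure needs a suspect role and a name hit in drugname or prod_ai", {
  drug <- data.frame(
    primaryid = c("1", "2", "3", "4", "5"),
    drug_seq = "1",
    role_cod = c("PS", "PS", "C", "SS", "PS"),
    drugname = c("VEKLURY", "REMDESIVIR 100MG", "remdesivir",
                 "REMDESIVIR", "IBUPROFEN"),
    prod_ai = c("", "", "", "", "REMDESIVIR"))
  expect_setequal(assign_exposure(drug, roles = "PS"), c("1", "2", "5"))
  expect_setequal(assign_exposure(drug, roles = c("PS", "SS")),
                  c("1", "2", "4", "5"))
})

test_that("outcomes collapse to the most serious code", {
  expect_equal(collapse_outcome(c("DE", "HO")), "DE")
  expect_equal(collapse_outcome("OT"), "OT")
  expect_equal(collapse_outcome(c("LT", "HO", "OT")), "LT")
  expect_equal(collapse_outcome(character(0)), "none")
  expect_equal(collapse_outcome(c("RI", "CA", "DS")), "DS")
})

test_that("planted group sizes and event counts are recovered exactly", {
  scn <- generate_scenario(scenario_config(
    100, 300, true_or = 2, baseline_event_prob = 0.1,
    n_events_exposed = 20L, n_events_control = 15L, seed = 9))
  cohort <- run_pipeline(scn$tables, covid_q, aki_n)
  flow <- attr(cohort, "flow")
  expect_equal(flow$n_exposed, 100L)
  expect_equal(flow$n_control, 300L)
  expect_equal(flow$events_exposed, 20L)
  expect_equal(flow$events_control, 15L)
  expect_equal(unname(cohort_ror(cohort)$a), 20)
})

test_that("groups partition the post-exclusion indication case set", {
  scn <- generate_scenario(scenario_config(120, 250, true_or = 2,
                                           baseline_event_prob = 0.15,
                                           preexisting_event_prob = 0.05,
                                           dup_version_prob = 0.2,
                                           n_noncovid = 40, seed = 10))
  cohort <- run_pipeline(scn$tables, covid_q, aki_n)
  flow <- attr(cohort, "flow")
  expect_equal(flow$n_exposed + flow$n_control,
               flow$indication_cases - flow$preexisting_excluded)
  expect_equal(anyDuplicated(cohort$caseid), 0L)
  truth <- scn$truth$cases
  expect_setequal(cohort$caseid, truth$caseid[!truth$preexisting])
  # exposure labels agree with the plant case by case
  m <- match(cohort$caseid, truth$caseid)
  expect_equal(cohort$exposure, truth$exposure[m])
  expect_equal(cohort$event, truth$event[m])
})

test_that("the pipeline recovers the planted 2x2 table", {
  scn <- generate_scenario(scenario_config(400, 900, true_or = 3,
                                           baseline_event_prob = 0.08,
                                           dup_version_prob = 0.15,
                                           partial_date_prob = 0.2,
                                           preexisting_event_prob = 0.01,
                                           n_noncovid = 50, seed = 12))
  cohort <- run_pipeline(scn$tables, covid_q, aki_n)
  r <- cohort_ror(cohort)
  expect_equal(c(a = r$a, b = r$b, c = r$c, d = r$d),
               as.numeric(scn$truth$table), ignore_attr = TRUE)
})

test_that("broad event scope never decreases per-group event counts", {
  scn <- generate_scenario(scenario_config(200, 400, true_or = 2,
                                           baseline_event_prob = 0.1,
                                           seed = 13))
  narrow <- run_pipeline(scn$tables, covid_q, aki_n,
                         plan = sensitivity_plan("main"))
  broad <- run_pipeline(scn$tables, covid_q, aki_b,
                        plan = sensitivity_plan("broad-event"))
  fn <- attr(narrow, "flow"); fb <- attr(broad, "flow")
  expect_gte(fb$events_exposed, fn$events_exposed)
  expect_gte(fb$events_control, fn$events_control)
})

test_that("an index-drug case never lands in the named control group", {
  tabs <- empty_tables()
  tabs <- add_case(tabs, "1", drugname = c("REMDESIVIR",
                                           "HYDROXYCHLOROQUINE"),
                   role = c("PS", "PS"))
  tabs <- add_case(tabs, "2", drugname = "HYDROXYCHLOROQUINE",
                   pts = "Pyrexia")
  tabs <- add_case(tabs, "3", drugname = "IBUPROFEN", pts = "Pyrexia")
  cohort <- run_pipeline(tabs, covid_q, aki_n,
                         plan = sensitivity_plan("named-controls"))
  expect_equal(cohort$exposure[cohort$caseid == "1"], "remdesivir")
  expect_equal(cohort$exposure[cohort$caseid == "2"], "control")
  # case 3's suspect drug is outside the named list: dropped
  expect_false("3" %in% cohort$caseid)
})

test_that("covariates and outcome land in the cohort row", {
  tabs <- empty_tables()
  tabs <- add_case(tabs, "1", outc = c("HO", "DE"), age = "24",
                   age_cod = "MON", sex = "", occp = "CN", country = "")
  cohort <- run_pipeline(tabs, covid_q, aki_n)
  expect_equal(cohort$outcome, "DE")
  expect_equal(cohort$age_band, "<18")
  expect_equal(cohort$sex, "Unknown")
  expect_equal(cohort$reporter, "Non-health professional")
  expect_equal(cohort$country, "Unknown")
})

test_that("an empty flow stage is a hard error", {
  tabs <- empty_tables()
  tabs <- add_case(tabs, "1", indi = c("COVID-19", "Acute kidney injury"))
  expect_error(run_pipeline(tabs, covid_q, aki_n), "pre-existing")
})
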