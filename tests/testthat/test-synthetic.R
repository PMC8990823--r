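test_that("identical seeds produce byte-identical tables and files", {
  cfg <- scenario_config(60, 120, true_or = 2, baseline_event_prob = 0.2,
                         dup_version_prob = 0.2, partial_date_prob = 0.2,
                         n_noncovid = 20, seed = 51)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(s1, d1); write_scenario(s2, d2)
  for (k in faers_table_kinds) {
    f <- paste0(k, ".txt")
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(scenario_config(0, 10), "positive")
  expect_error(scenario_config(10, 10, baseline_event_prob = 0), "0,1")
  expect_error(scenario_config(10, 10, true_or = -2), "positive")
  expect_error(scenario_config(10, 10, dup_version_prob = 1.2), "0,1")
  cf <- default_confounders()
  cf$sex$prob_control <- c(0.5, 0.4, 0.4)
  expect_error(scenario_config(10, 10, confounders = cf), "distribution")
  expect_error(scenario_config(10, 10, confounders = list()),
               "age_band")
})

test_that("dedup output equals the ground-truth unique case count", {
  cfg <- scenario_config(200, 300, true_or = 2, baseline_event_prob = 0.1,
                         dup_version_prob = 0.25, n_noncovid = 40,
                         seed = 52)
  scn <- generate_scenario(cfg)
  dd <- deduplicate(scn$tables$demo)
  expect_equal(dd$report$output_count,
               scn$truth$n_cases + scn$truth$n_noncovid)
  expect_equal(dd$report$exact_duplicates_removed,
               scn$truth$n_exact_duplicates)
  expect_equal(dd$report$versions_collapsed, scn$truth$n_extra_versions)
  # the surviving version is always the latest one (version suffix 2)
  expect_true(all(endsWith(dd$records$primaryid, "2")))
})

test_that("exposed-arm event probability follows the odds transform", {
  cfg <- scenario_config(10, 10, true_or = 3, baseline_event_prob = 0.06)
  expect_equal(cfg$p_event_exposed,
               3 * (0.06 / 0.94) / (1 + 3 * (0.06 / 0.94)),
               tolerance = 1e-12)
})

test_that("null scenario: pipeline ROR interval contains 1", {
  scn <- generate_scenario(null_scenario(seed = 1))
  cohort <- run_pipeline(scn$tables, bundled_smq("covid19"),
                         bundled_smq("aki"))
  r <- cohort_ror(cohort)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
})

test_that("generated tables carry the planted per-case structure", {
  cfg <- scenario_config(80, 160, true_or = 2, baseline_event_prob = 0.25,
                         multi_pt_prob = 0.5, multi_outcome_prob = 0.5,
                         seed = 53)
  scn <- generate_scenario(cfg)
  truth <- scn$truth$cases
  # outcome rows collapse back to the planted primary outcome
  outc <- scn$tables$outc
  for (i in which(truth$outcome != "none")[1:20]) {
    codes <- outc$outc_cod[outc$primaryid == truth$primaryid[i]]
    expect_equal(collapse_outcome(codes), truth$outcome[i])
  }
  # event cases have at least one event PT, non-event cases none
  aki <- bundled_smq("aki", "narrow")
  hit <- match_cases(scn$tables$reac, aki)
  expect_setequal(intersect(hit, truth$primaryid),
                  truth$primaryid[truth$event])
})
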