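# faersvig

Pharmacovigilance disproportionality analysis for FAERS spontaneous
reports: a tested, end-to-end R pipeline for detecting adverse-event
signals of a drug within an indication-defined reporting cohort. The
motivating analysis is acute kidney injury (AKI) under remdesivir among
COVID-19 reports, but every stage is parameterised: any indication SMQ,
event SMQ and index-drug name list can be supplied.

## What it does

Spontaneous-report databases have no denominator, so safety signals are
sought through *disproportionality*. On the drug × event 2×2 table of
report counts (a = index drug & event, b = index drug & no event,
c = control & event, d = control & no event) the package computes the
reporting odds ratio

    ROR = (a·d) / (b·c),   95% CI = exp( ln ROR ± z·√(1/a + 1/b + 1/c + 1/d) )

with the uncorrected Pearson χ² and the signal criterion
"lower 95% bound > 1", before and after 1:1 propensity-score matching on
age band, sex, reporter type and occurrence country (caliper 0.001,
exact-then-optimal matching without replacement).

The pipeline stages, each an exported function:

| stage | function(s) |
|---|---|
| FAERS quarterly-extract I/O ("$"-delimited, 7 tables) | `read_faers_table`, `write_faers_table` |
| FDA-recommended case deduplication | `deduplicate`, `filter_to_cases` |
| SMQ case/event identification, pre-existing exclusion | `read_smq`, `match_cases`, `exclude_preexisting` |
| cohort construction + sensitivity plans | `build_cohort`, `run_pipeline`, `sensitivity_plan` |
| contingency statistics | `ror_2x2`, `pearson_rxc`, `fisher_2x2`, `choose_test` |
| propensity matching + balance | `estimate_propensity`, `match_pairs`, `psm_match`, `balance_table` |
| time-to-onset and serious outcomes | `onset_days`, `onset_by_group`, `outcome_comparison` |
| synthetic FAERS generator with ground truth | `scenario_config`, `generate_scenario`, `paper_scale_scenario` |

A thin command-line wrapper (`inst/scripts/faersvig`) exposes
`simulate`, `dedup` and `signal` subcommands over the same functions.

## Worked example

Generate a synthetic FAERS quarter with a planted odds ratio of 3,
run the pipeline, and match:

```r
library(faersvig)

cfg <- scenario_config(n_exposed = 4000, n_control = 9000,
                       true_or = 3, baseline_event_prob = 0.06,
                       confounders = no_confounding(), seed = 11)
scn <- generate_scenario(cfg)

cohort <- run_pipeline(scn$tables,
                       covid_query = bundled_smq("covid19"),
                       aki_query   = bundled_smq("aki", "narrow"))
cohort_ror(cohort)
#> 2x2 table: a=624 b=3376 c=540 d=8460
#> ROR 2.90, 95% CI (2.56, 3.27)
#> Pearson chi2 313.06, p 4.7e-70 (chi-square) -- SIGNAL (lower CI bound > 1)

scn$truth$table       # the planted table, recovered exactly
#>    a    b    c    d
#>  624 3376  540 8460
```

The recovered table equals the generator's ground truth; the estimated
ROR 2.90 brackets the planted odds ratio 3 within its interval. On the
reference counts the same machinery prints:

```r
ror_2x2(589, 3402, 516, 8362)
#> 2x2 table: a=589 b=3402 c=516 d=8362
#> ROR 2.81, 95% CI (2.48, 3.18)
#> Pearson chi2 280.73, p 5.2e-63 (chi-square) -- SIGNAL (lower CI bound > 1)
```

meaning: AKI is reported 2.81 times more disproportionately with the
index drug than with comparator drugs in the cohort, and the association
persists (3.85) in the matched set.

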