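---
title: "Disproportionality analysis of FAERS spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersvig)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary post-marketing reports of suspected
adverse drug reactions. They have no denominator — we observe reports,
not patients at risk — so drug safety signals are sought through
*disproportionality*: is an adverse event reported disproportionately
often with an index drug compared with other drugs, within a comparable
reporting population?

`faersvig` implements that workflow for the motivating use case of acute
kidney injury (AKI) under remdesivir in COVID-19 reports, as a general,
parameterised pipeline: any indication SMQ, event SMQ and index-drug name
list can be supplied.

## The pipeline, stage by stage

### Ingestion (`read_faers_table`)

FAERS quarters ship as seven "$"-delimited ASCII tables (DEMO, DRUG,
REAC, OUTC, RPSR, THER, INDI). The reader keeps every field as a
character string. This is deliberate: FAERS dates are yyyymmdd strings
that are frequently partial ("202004") or empty, and each downstream
stage has its own rule for what to do with them. Resolving dates at
ingestion would force one rule on all stages. Lines whose field count
does not match the header are skipped and counted in a parse report, so
`records + skipped` always equals the number of data lines.

### Deduplication (`deduplicate`)

A FAERS case (CASEID) accumulates report versions (PRIMARYID). The
FDA-recommended reduction is applied in three steps: byte-identical DEMO
rows collapse to one; within a CASEID only the latest FDA_DT survives;
among ties, only the highest PRIMARYID survives. Two numerical choices
were open:

* Partial FDA_DT values are right-padded with zeros to 8 digits before
  lexicographic comparison, which coincides with chronological order for
  valid dates and sorts a partial month ("202004" → "20200400") before
  any real day in that month.
* PRIMARYID order is numeric when every id parses as a number (the
  intended "lower id" semantics), falling back to lexicographic order
  otherwise.

After step three no further tie is possible within a case except for
rows differing only in non-key fields; the last such row in input order
is kept, and the property-based tests pin this to an independent
group-sort-take-last oracle. Child tables are filtered to surviving
PRIMARYIDs afterwards; the reduction itself sees DEMO only.

### SMQ identification (`match_cases`)

Cases and events are identified by matching preferred terms (PTs)
against Standardised MedDRA Query term lists: the indication SMQ against
INDI, the event SMQ against REAC. Matching is case-insensitive *exact*
matching on trimmed text — PTs are a controlled vocabulary, and
substring matching would over-capture (e.g. "renal failure" inside
"prerenal failure"). A case reporting several matching PTs counts once.
Cases whose *indications* match the event SMQ describe a pre-existing
condition and are excluded.

MedDRA is licensed, so the package cannot ship the production term
lists. It bundles placeholder lists of the reference cardinalities (18
narrow COVID-19 PTs; 19 narrow and 52 broad AKI PTs), assembled from
public SMQ descriptions and labelled synthetic in their file names;
every pipeline function takes the query as a parameter, so users with a
MedDRA licence drop in the real lists unchanged.

### Cohort construction (`build_cohort`)

Exposure is assigned from DRUG rows whose role code is primary suspect
(PS) and whose `drugname` *or* `prod_ai` contains one of the index-drug
names, case-insensitively. Containment rather than equality is used
because FAERS drug names are free text with dose and salt suffixes
("REMDESIVIR 100MG"). The control group is every remaining cohort case
(or, under the named-comparator sensitivity plan, the cases whose
primary suspect matches a five-drug list). An index-exposed case can
never enter the control group — the groups must partition the cohort
for the reporting odds ratio to be well defined.

Covariates keep missingness as an explicit "Unknown" level — an
independent classification, never imputed — because missingness in
spontaneous reports is informative (it differs strongly by reporting
country and reporter type). Multiple outcome codes collapse to the most
serious by the order DE > LT > HO > DS > CA > RI > OT; the first two
positions are fixed by the reference worked example (death over
hospitalization), and the remainder adopts the conventional seriousness
listing order.

Four analysis plans are bundled (`sensitivity_plan`): the main analysis
(narrow event SMQ, PS-only, all-other-drugs control) and three
sensitivity variants (broad event SMQ; PS+SS exposure; named
comparators).

### Disproportionality (`ror_2x2`)

On the 2×2 table (a = index & event, b = index & no event, c = control &
event, d = control & no event):

* ROR = (ad)/(bc);
* 95% CI = exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d)) (Woolf), with z the
  exact 0.975 normal quantile 1.959964 — at 2-decimal reporting this is
  indistinguishable from 1.96;
* the uncorrected Pearson χ² = N(ad − bc)²/((a+b)(c+d)(a+c)(b+d)); no
  Yates continuity correction, which the reference values confirm;
* signal criterion: lower 95% bound above 1.

A zero cell makes the Woolf variance undefined; the result is then
computed with the Haldane–Anscombe +0.5 correction and flagged
`degenerate` rather than silently corrected. Sparse tables (any expected
count below 5) switch the p-value to Fisher's exact test, computed by
hypergeometric summation of tables no more probable than the observed
one.

### Propensity-score matching (`psm_match`)

The propensity score is a main-effects logistic regression of exposure
on the four categorical covariates (age band, sex, reporter type,
country), Unknown levels included. Matching is 1:1 without replacement
under a caliper of 0.001 on the probability scale, in two stages that
mirror the exact + fuzzy behaviour of common PSM implementations:

1. *Exact stage*: reports agreeing on every covariate level are paired
   directly (under a main-effects model they have identical scores, so
   the within-pair distance is 0), in caseid order within stratum.
2. *Fuzzy stage*: the remainder is matched optimally on score distance.
   Because the cost is |x − y| on a line, an optimal caliper matching
   can always be taken non-crossing (uncrossing two pairs never
   increases the total distance nor either pair's distance, so caliper
   feasibility is preserved). The non-crossing optimum — maximum pair
   count first, minimum total distance second — is computed by an
   O(mn) dynamic program in C++ over the two score-sorted lists, and is
   verified against exhaustive search over all pairings in the test
   suite. Ties are broken by lower caseid, so the whole procedure is
   deterministic; no generic assignment solver or greedy heuristic is
   involved.

`balance_table` reports per-level counts and percentages, an r×c Pearson
χ² per covariate, and the maximum absolute standardised difference over
levels — the test suite requires matching to reduce it for every
covariate on a confounded scenario.

No claim is made of replicating any particular external matched-set
size: optimal matching is unique only up to ties, and other
implementations order and break ties differently. What is contracted —
and tested — is the statistical definition above.

### Time to onset and outcomes (`onset_days`, `outcome_comparison`)

Time to onset is EVENT_DT − START_DT in whole calendar days. Reports
without full 8-digit dates on both sides are excluded
(`partial_date` / `invalid_date`), as are events dated strictly before
drug start (`negative_interval`); same-day onset is 0 days and is kept.
When a case has several therapy rows for the suspect drug, the earliest
valid full start date is used. Every input record is either included or
excluded with a reason, and the cumulative-onset curve is non-decreasing
and reaches 1 at the last observed day.

The outcome comparison tabulates each serious outcome code against event
status within a group, restricted to reports with outcome data, choosing
Pearson χ² or Fisher's exact test by the expected-count-below-5 rule.

## The synthetic-data generator

`generate_scenario` emulates the statistical structure the analysis
assumes: binary exposure, binary event with a controllable odds ratio,
four categorical covariates with per-arm distributions (confounding) and
optional log-odds effects on exposure and event, duplicate report
versions (byte-identical rows, earlier-FDA_DT versions, same-FDA_DT
lower-PRIMARYID versions), partial dates, pre-existing conditions,
non-indication noise reports, multi-PT and multi-outcome cases, and
exponential onset times (rounded to whole days, which keeps the expected
value at the target mean to three digits). Design choices:

* The exposed-arm event probability is derived from the target odds
  ratio by the odds transform; when covariates carry event effects,
  per-arm intercepts are re-calibrated by root-finding so the arm-level
  event probabilities still hit their targets. This keeps the expected
  2×2 table exactly at its nominal margins while leaving the covariates
  genuinely confounded.
* `paper_scale_scenario()` is calibrated once to the reference cohort
  scale: groups 3,991/8,878, control event probability 516/8,878, target
  OR (589×8362)/(3402×516), age/sex event effects on, duplicate/partial/
  pre-existing rates at realistic levels. `null_scenario()` is the
  no-association, no-confounding control at 10,000 reports per arm.
* Generation is bit-reproducible given the seed; the ground-truth ledger
  records every planted per-case label, so pipeline tests compare
  recovered quantities against the plant exactly.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real FAERS data: reporting-rate dynamics and
stimulated reporting, drug-name misspellings, fuzzy duplicates across
different CASEIDs, correlated multi-drug regimens, and country-specific
coding habits. Tests on generated data validate the *machinery*, not
the epidemiology of any real quarter.

## Problem sizes and numerical conventions

The bundled test suite runs the full pipeline repeatedly at moderate
scale (up to 13,000 reports per replicate; 200 replicates for the
odds-ratio recovery check, which brackets the mean recovered ROR within
5% of the target 3) and verifies the matcher, the Fisher p-value and the
deduplication against brute-force oracles at small sizes where
exhaustive search is exact. Confidence-interval coverage is checked over
2,000 simulated tables (300 reports per arm, event probabilities ≥
0.05), requiring empirical coverage in 93–97%. The exact matcher's
dynamic program allocates (m+1)×(n+1) cells and refuses instances beyond
4×10⁸ cells; cohorts of the reference scale fit comfortably.

## Known limitations

* The bundled SMQ lists are placeholders of the correct cardinality, not
  licensed MedDRA content; absolute case counts on real data depend on
  the real lists.
* Exposure matching is name-containment, not RxNorm normalisation;
  exotic spellings of a drug name are missed.
* The control group under the main plan excludes only PS-exposed (or
  PS/SS-exposed, per plan) index-drug cases; an index drug recorded as
  concomitant does not remove a case from the controls.
* Onset analysis reports means, SDs and cumulative proportions only; no
  censoring model is attempted, because a spontaneous report has no
  follow-up window.
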