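#' @title Cohort construction: exposure, events, covariates, outcomes
#' @name cohort
#' @description
#' The analysis cohort is the set of deduplicated reports with the
#' indication of interest (COVID-19, narrow SMQ on INDI), minus reports in
#' which the adverse event of interest already appears among the
#' indications (a pre-existing condition). Reports whose primary-suspect
#' drug matches the index-drug name list form the exposed group; the
#' remaining reports form the control group (all other primary suspects, or
#' a named comparator list under the corresponding sensitivity plan).
#' Missing demographics are kept as an explicit "Unknown" category
#' throughout.
NULL

#' Severity-ordered serious outcome codes
#'
#' DE death, LT life-threatening, HO hospitalization, DS disability,
#' CA congenital anomaly, RI required intervention, OT other serious.
#' @export
outcome_severity <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Default index-drug and named-comparator name lists
#' @name drug_lists
#' @export
remdesivir_names <- c("remdesivir", "veklury")

#' @rdname drug_lists
#' @export
named_control_drugs <- c("hydroxychloroquine", "azithromycin",
                         "bamlanivimab", "tocilizumab",
                         "lopinavir\\ritonavir")

#' Sensitivity analysis plans
#'
#' The main analysis uses the narrow event SMQ, primary-suspect (PS) role
#' only, and all other primary suspects as control. The three sensitivity
#' variants are: broad event SMQ; PS or secondary-suspect (SS) exposure;
#' and the named five-drug comparator control group.
#'
#' @param name one of "main", "broad-event", "ps-ss", "named-controls".
#' @return list with `event_scope`, `suspect_roles`, `control_mode`.
#' @export
sensitivity_plan <- function(name = c("main", "broad-event", "ps-ss",
                                      "named-controls")) {
  name <- match.arg(name)
  plan <- switch(name,
    "main"           = list(event_scope = "narrow", suspect_roles = "PS",
                            control_mode = "all-other-drugs"),
    "broad-event"    = list(event_scope = "broad", suspect_roles = "PS",
                            control_mode = "all-other-drugs"),
    "ps-ss"          = list(event_scope = "narrow",
                            suspect_roles = c("PS", "SS"),
                            control_mode = "all-other-drugs"),
    "named-controls" = list(event_scope = "narrow", suspect_roles = "PS",
                            control_mode = "named-drug-list"))
  plan$name <- name
  plan
}

#' Identify exposed reports by suspect-drug name
#'
#' A report is exposed when any of its DRUG rows has a role code in `roles`
#' and a `drugname` or `prod_ai` containing (case-insensitively) one of the
#' names. Containment rather than equality is used because FAERS drug names
#' are free text with dose and salt suffixes ("REMDESIVIR 100MG").
#'
#' @param drug_records DRUG table.
#' @param names character vector of drug identifiers.
#' @param roles role codes, default primary suspect only.
#' @return character vector of exposed primaryids.
#' @export
assign_exposure <- function(drug_records, names = remdesivir_names,
                            roles = "PS") {
  in_role <- toupper(trimws(as.character(drug_records$role_cod))) %in% roles
  txt <- tolower(paste(drug_records$drugname, drug_records$prod_ai))
  hit <- rep(FALSE, nrow(drug_records))
  for (nm in tolower(names)) {
    hit <- hit | grepl(nm, txt, fixed = TRUE)
  }
  unique(as.character(drug_records$primaryid[in_role & hit]))
}

#' Collapse a report's outcome codes to the most serious one
#'
#' Severity order DE > LT > HO > DS > CA > RI > OT; a report with no outcome
#' rows maps to "none".
#'
#' @param outc_cod character vector of outcome codes for one report.
#' @return a single code, or "none".
#' @export
collapse_outcome <- function(outc_cod) {
  codes <- toupper(trimws(as.character(outc_cod)))
  codes <- codes[codes %in% outcome_severity]
  if (length(codes) == 0L) return("none")
  outcome_severity[min(match(codes, outcome_severity))]
}

# vectorised over reports: primaryid -> most serious code
.collapse_outcomes <- function(outc_records) {
  if (nrow(outc_records) == 0L) {
    return(data.frame(primaryid = character(0), outcome = character(0)))
  }
  rank <- match(toupper(trimws(outc_records$outc_cod)), outcome_severity)
  ok <- !is.na(rank)
  id <- as.character(outc_records$primaryid[ok])
  best <- tapply(rank[ok], id, min)
  data.frame(primaryid = names(best),
             outcome = outcome_severity[as.integer(best)],
             stringsAsFactors = FALSE)
}

.reporter_category <- function(occp_cod) {
  code <- toupper(trimws(as.character(occp_cod)))
  out <- rep("Unknown", length(code))
  out[code %in% c("MD", "PH", "OT", "HP")] <- "Health professional"
  out[code %in% c("CN", "LW")] <- "Non-health professional"
  out
}

# earliest valid full start date per report among the suspect drug's
# therapy rows; falls back to the minimum raw string (partial dates are
# excluded later, at the time-to-onset stage)
.suspect_start_dates <- function(drug_records, ther_records, suspect_rows) {
  if (nrow(ther_records) == 0L || !any(suspect_rows)) {
    return(data.frame(primaryid = character(0), start_dt = character(0)))
  }
  key_drug <- paste(as.character(drug_records$primaryid[suspect_rows]),
                    trimws(as.character(drug_records$drug_seq[suspect_rows])))
  seq_col <- if ("dsg_drug_seq" %in% names(ther_records)) "dsg_drug_seq"
             else "drug_seq"
  key_ther <- paste(as.character(ther_records$primaryid),
                    trimws(as.character(ther_records[[seq_col]])))
  th <- ther_records[key_ther %in% key_drug, , drop = FALSE]
  if (nrow(th) == 0L) {
    return(data.frame(primaryid = character(0), start_dt = character(0)))
  }
  sd <- trimws(as.character(th$start_dt))
  full <- grepl("^[0-9]{8}$", sd)
  id <- as.character(th$primaryid)
  # order: full dates first (chronological), then partials; take the first
  ord <- order(id, !full, sd, method = "radix")
  first <- !duplicated(id[ord])
  data.frame(primaryid = id[ord][first], start_dt = sd[ord][first],
             stringsAsFactors = FALSE)
}

#' Build the analysis cohort and the identification flow counts
#'
#' Runs the full identification flow on deduplicated tables: indication
#' matching, pre-existing-event exclusion, exposure assignment, control
#' selection, event flagging, covariate derivation and outcome collapsing.
#'
#' @param tables named list of FAERS tables (`demo`, `drug`, `reac`, `outc`,
#'   `ther`, `indi`; `rpsr` optional), already deduplicated and filtered
#'   with [deduplicate()] / [filter_to_cases()].
#' @param covid_query indication SMQ (narrow scope).
#' @param aki_query event SMQ at the scope of `plan$event_scope`; also used
#'   to exclude reports with the event among their indications.
#' @param plan a [sensitivity_plan()].
#' @param index_names,control_names drug name lists for the exposed group
#'   and (under `control_mode = "named-drug-list"`) the comparator group.
#' @return data.frame with one row per case: `caseid`, `primaryid`,
#'   `exposure` ("remdesivir"/"control"), logical `event`, `age_band`,
#'   `sex`, `reporter`, `country`, `outcome`, `event_dt`, `start_dt`;
#'   attribute `flow` holds the stage counts (indication cases found,
#'   pre-existing exclusions, group sizes, events per group).
#' @export
build_cohort <- function(tables, covid_query, aki_query,
                         plan = sensitivity_plan("main"),
                         index_names = remdesivir_names,
                         control_names = named_control_drugs) {
  demo <- tables$demo
  covid_ids <- match_cases(tables$indi, covid_query)
  n_covid <- length(covid_ids)
  kept <- exclude_preexisting(covid_ids, tables$indi, aki_query)
  n_pre <- length(attr(kept, "excluded"))
  if (length(kept) == 0L) {
    stop("cohort empty after the pre-existing-event exclusion stage")
  }

  exposed <- intersect(
    assign_exposure(tables$drug, index_names, plan$suspect_roles), kept)
  if (plan$control_mode == "named-drug-list") {
    named <- assign_exposure(tables$drug, control_names, plan$suspect_roles)
    control <- setdiff(intersect(named, kept), exposed)
  } else {
    control <- setdiff(kept, exposed)
  }
  ids <- c(exposed, control)
  if (length(ids) == 0L) stop("cohort empty after exposure assignment")

  event_ids <- match_cases(tables$reac, aki_query)

  demo <- demo[match(ids, as.character(demo$primaryid)), , drop = FALSE]
  if (anyNA(demo$primaryid)) {
    stop("cohort reports missing from the DEMO table")
  }
  sex <- toupper(trimws(as.character(demo$sex)))
  sex[!sex %in% c("F", "M")] <- "Unknown"
  country <- toupper(trimws(as.character(demo$occr_country)))
  country[!nzchar(country)] <- "Unknown"

  suspect_rows <-
    toupper(trimws(as.character(tables$drug$role_cod))) %in%
      plan$suspect_roles
  starts <- .suspect_start_dates(tables$drug, tables$ther, suspect_rows)
  outcomes <- .collapse_outcomes(tables$outc)

  cohort <- data.frame(
    caseid = as.character(demo$caseid),
    primaryid = as.character(demo$primaryid),
    exposure = ifelse(ids %in% exposed, "remdesivir", "control"),
    event = ids %in% event_ids,
    age_band = age_band(normalize_age(demo$age, demo$age_cod)),
    sex = sex,
    reporter = .reporter_category(demo$occp_cod),
    country = country,
    outcome = {
      m <- match(ids, outcomes$primaryid)
      ifelse(is.na(m), "none", outcomes$outcome[m])
    },
    event_dt = trimws(as.character(demo$event_dt)),
    start_dt = {
      m <- match(ids, starts$primaryid)
      ifelse(is.na(m), "", starts$start_dt[m])
    },
    stringsAsFactors = FALSE
  )

  attr(cohort, "flow") <- list(
    indication_cases = n_covid,
    preexisting_excluded = n_pre,
    n_exposed = length(exposed),
    n_control = length(control),
    events_exposed = sum(cohort$event[cohort$exposure == "remdesivir"]),
    events_control = sum(cohort$event[cohort$exposure == "control"]),
    plan = plan$name
  )
  cohort
}

#' Deduplicate raw tables and build a cohort in one step
#'
#' Convenience wrapper: [deduplicate()] on DEMO, [filter_to_cases()] on the
#' child tables, then [build_cohort()].
#'
#' @inheritParams build_cohort
#' @param tables named list of raw FAERS tables.
#' @return the cohort, with additional attribute `dedup_report`.
#' @export
run_pipeline <- function(tables, covid_query, aki_query,
                         plan = sensitivity_plan("main"),
                         index_names = remdesivir_names,
                         control_names = named_control_drugs) {
  dd <- deduplicate(tables$demo)
  tabs <- filter_to_cases(tables[setdiff(names(tables), "demo")],
                          dd$records$primaryid)
  tabs$demo <- dd$records
  cohort <- build_cohort(tabs, covid_query, aki_query, plan,
                         index_names, control_names)
  attr(cohort, "dedup_report") <- dd$report
  cohort
}
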