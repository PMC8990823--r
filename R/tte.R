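#' @title Time-to-onset and serious-outcome analyses
#' @name tte
#' @description
#' Time to onset is the calendar-day difference between the adverse-event
#' date (EVENT_DT, DEMO table) and the suspect drug's start date (START_DT,
#' THER table). FAERS dates may be partial; only reports with full
#' yyyymmdd values for both dates enter the calculation, and reports with
#' the event dated strictly before the drug start are excluded as
#' implausible. Same-day onset yields 0 days and is kept.
NULL

#' Days from drug start to event onset, with exclusion reasons
#'
#' @param event_dt,start_dt character vectors of yyyymmdd date strings
#'   (recycled to a common length).
#' @return data.frame with `days` (integer, `NA` when excluded) and
#'   `reason` (`NA`, "partial_date", "invalid_date", "negative_interval").
#'   `sum(!is.na(days)) + sum(!is.na(reason))` equals the input length.
#' @examples
#' onset_days("20200410", "20200405")  # 5 days
#' onset_days("202004",   "20200405")  # excluded: partial_date
#' @export
onset_days <- function(event_dt, start_dt) {
  n <- max(length(event_dt), length(start_dt))
  ev <- trimws(as.character(rep_len(event_dt, n)))
  st <- trimws(as.character(rep_len(start_dt, n)))
  reason <- rep(NA_character_, n)
  days <- rep(NA_integer_, n)

  full <- grepl("^[0-9]{8}$", ev) & grepl("^[0-9]{8}$", st)
  reason[!full] <- "partial_date"

  evd <- as.Date(ifelse(full, ev, NA), format = "%Y%m%d")
  std <- as.Date(ifelse(full, st, NA), format = "%Y%m%d")
  bad <- full & (is.na(evd) | is.na(std))   # e.g. month 13, day 32
  reason[bad] <- "invalid_date"

  ok <- full & !bad
  d <- as.integer(evd[ok] - std[ok])
  neg <- d < 0L
  reason[ok][neg] <- "negative_interval"
  days[ok][!neg] <- d[!neg]
  data.frame(days = days, reason = reason, stringsAsFactors = FALSE)
}

#' Onset summary: mean, SD and cumulative-onset curve
#'
#' @param days integer vector of onset days (exclusions already removed).
#' @return list with `n`, `mean`, `sd` (sample SD, n-1 denominator; `NA`
#'   for fewer than 2 observations) and `curve`, a data.frame
#'   (`day`, `cumulative_proportion`) over the observed day range; the
#'   proportion at day t is the fraction of onsets occurring within t days,
#'   non-decreasing and reaching 1 at the maximum observed day.
#' @export
onset_summary <- function(days) {
  days <- days[!is.na(days)]
  n <- length(days)
  if (n == 0L) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                curve = data.frame(day = integer(0),
                                   cumulative_proportion = numeric(0))))
  }
  ds <- 0:max(days)
  curve <- data.frame(
    day = ds,
    cumulative_proportion = vapply(ds, function(t) mean(days <= t),
                                   numeric(1)))
  list(n = n, mean = mean(days),
       sd = if (n >= 2L) sd(days) else NA_real_,
       curve = curve)
}

#' Compute onset summaries per exposure group from a cohort
#'
#' Restricts to event cases, applies [onset_days()] to their event and
#' suspect-drug start dates, and summarises each group.
#'
#' @param cohort cohort data.frame from [build_cohort()].
#' @return list per group ("remdesivir", "control"), each as
#'   [onset_summary()] output plus an `excluded` reason count table;
#'   `included + excluded` equals that group's event-case count.
#' @export
onset_by_group <- function(cohort) {
  ev <- cohort[cohort$event, , drop = FALSE]
  out <- list()
  for (g in c("remdesivir", "control")) {
    rows <- ev[ev$exposure == g, , drop = FALSE]
    od <- onset_days(rows$event_dt, rows$start_dt)
    s <- onset_summary(od$days)
    s$excluded <- table(od$reason)
    out[[g]] <- s
  }
  out
}

#' Serious-outcome comparison between event and non-event cases
#'
#' For one exposure group, restricted to reports with outcome data, builds
#' for each serious outcome code the 2x2 table (outcome vs any other
#' outcome, by event status), with column percentages, the test chosen by
#' [choose_test()] (uncorrected Pearson chi-square, or Fisher's exact for
#' sparse tables) and its p-value.
#'
#' @param cohort cohort data.frame.
#' @param group "remdesivir" or "control".
#' @return data.frame, one row per outcome code: counts and column
#'   percentages for event and non-event cases, `test`, `p`; attribute
#'   `totals` holds the per-column denominators.
#' @export
outcome_comparison <- function(cohort, group = c("remdesivir", "control")) {
  group <- match.arg(group)
  sub <- cohort[cohort$exposure == group & cohort$outcome != "none", ,
                drop = FALSE]
  n_ev <- sum(sub$event)
  n_no <- sum(!sub$event)
  rows <- lapply(outcome_severity, function(code) {
    a <- sum(sub$event & sub$outcome == code)
    c_ <- sum(!sub$event & sub$outcome == code)
    tab <- matrix(c(a, n_ev - a, c_, n_no - c_), 2, 2)
    test <- NA_character_; p <- NA_real_
    if (n_ev > 0 && n_no > 0) {
      test <- choose_test(tab)
      p <- if (test == "fisher") fisher_2x2(a, n_ev - a, c_, n_no - c_)
           else pearson_rxc(tab)$p
    }
    data.frame(outcome = code,
               n_event = a,
               pct_event = if (n_ev > 0) 100 * a / n_ev else NA_real_,
               n_nonevent = c_,
               pct_nonevent = if (n_no > 0) 100 * c_ / n_no else NA_real_,
               test = test, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(event = n_ev, nonevent = n_no)
  out
}
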