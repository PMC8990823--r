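#' @title Synthetic FAERS scenario generator with known ground truth
#' @name synthetic_data
#' @description
#' Generates the seven FAERS quarterly-extract tables for a two-group
#' cohort with a controllable drug-event odds ratio, demographic
#' confounding, duplicate report versions, partial dates, pre-existing
#' conditions and serious outcomes — together with a ground-truth ledger of
#' every planted quantity, so each pipeline stage can be tested end-to-end
#' without any download. Event probability in the exposed arm is derived
#' from the target odds ratio and the control-arm probability via the odds
#' transform; when covariates carry event effects, per-arm intercepts are
#' calibrated so the arm-level event probabilities still hit their targets.
#' Generation is bit-reproducible for a given seed.
NULL

.generic_pts <- c("Pyrexia", "Cough", "Fatigue", "Nausea", "Headache",
                  "Dyspnoea", "Diarrhoea", "Vomiting")
.noncovid_indications <- c("Hypertension", "Diabetes mellitus",
                           "Rheumatoid arthritis")
.control_drug_pool <- c("HYDROXYCHLOROQUINE", "AZITHROMYCIN", "BAMLANIVIMAB",
                        "TOCILIZUMAB", "LOPINAVIR\\RITONAVIR",
                        "DEXAMETHASONE", "FAVIPIRAVIR")

# raw (case-preserving) preferred terms from a bundled synthetic SMQ list
.bundled_pts <- function(smq = c("covid19", "aki"),
                         scope = c("narrow", "broad")) {
  smq <- match.arg(smq); scope <- match.arg(scope)
  file <- switch(smq, covid19 = "smq_covid19_synthetic.csv",
                 aki = "smq_acute_kidney_injury_synthetic.csv")
  df <- read.csv(system.file("extdata", file, package = "faersvig",
                             mustWork = TRUE), colClasses = "character")
  if (scope == "narrow") df <- df[df$scope == "narrow", , drop = FALSE]
  df$pt
}

#' Default demographic confounder structure
#'
#' Four categorical covariates with per-arm level probabilities emulating
#' the demographic imbalance of a real remdesivir/comparator cohort (the
#' index drug skews older, more male, more health-professional-reported and
#' strongly towards the US), plus optional per-level log-odds effects on
#' the event and on exposure (all zero by default).
#'
#' @return named list, one element per covariate, each with `levels`,
#'   `prob_exposed`, `prob_control`, `event_logodds`, `exposure_logodds`.
#' @export
default_confounders <- function() {
  cf <- list(
    age_band = list(
      levels = c("<18", "18-44", "45-64", ">=65", "Unknown"),
      prob_exposed = c(0.014, 0.153, 0.318, 0.476, 0.039),
      prob_control = c(0.019, 0.133, 0.306, 0.360, 0.182)),
    sex = list(
      levels = c("F", "M", "Unknown"),
      prob_exposed = c(0.384, 0.604, 0.012),
      prob_control = c(0.312, 0.538, 0.150)),
    reporter = list(
      levels = c("Health professional", "Non-health professional",
                 "Unknown"),
      prob_exposed = c(0.959, 0.013, 0.028),
      prob_control = c(0.845, 0.086, 0.069)),
    country = list(
      levels = c("US", "ES", "FR", "IT", "JP", "BR", "PT", "GB", "XX"),
      prob_exposed = c(0.939, 0.003, 0.008, 0.003, 0.009, 0.004, 0.011,
                       0.003, 0.020),
      prob_control = c(0.375, 0.156, 0.113, 0.109, 0.019, 0.014, 0.008,
                       0.012, 0.194))
  )
  lapply(cf, function(x) {
    x$event_logodds <- setNames(rep(0, length(x$levels)), x$levels)
    x$exposure_logodds <- setNames(rep(0, length(x$levels)), x$levels)
    x
  })
}

#' Remove confounding from a confounder structure
#'
#' Sets each covariate's exposed-arm level probabilities equal to the
#' control-arm ones and zeroes all log-odds effects.
#'
#' @param confounders a confounder list as from [default_confounders()].
#' @return the modified list.
#' @export
no_confounding <- function(confounders = default_confounders()) {
  lapply(confounders, function(x) {
    x$prob_exposed <- x$prob_control
    x$event_logodds[] <- 0
    x$exposure_logodds[] <- 0
    x
  })
}

.default_outcome_probs <- function() {
  list(
    event = c(DE = 0.30, LT = 0.06, HO = 0.14, DS = 0.005, CA = 0.001,
              RI = 0.01, OT = 0.29, none = 0.194),
    no_event = c(DE = 0.21, LT = 0.05, HO = 0.17, DS = 0.003, CA = 0.001,
                 RI = 0.005, OT = 0.33, none = 0.231))
}

#' Build and validate a synthetic-scenario configuration
#'
#' @param n_exposed,n_control case counts for the two arms.
#' @param true_or target odds ratio of the event given exposure.
#' @param baseline_event_prob control-arm event probability, in (0,1).
#' @param confounders per-covariate structure, see [default_confounders()].
#' @param dup_version_prob probability that a case carries an extra DEMO
#'   report version (split between byte-identical rows, earlier-FDA_DT
#'   versions, and same-FDA_DT lower-PRIMARYID versions).
#' @param partial_date_prob probability an event date is truncated to
#'   yyyymm (half that for start dates).
#' @param preexisting_event_prob probability a case lists the event among
#'   its indications (a pre-existing condition, excluded by the pipeline).
#' @param negative_interval_prob probability an event case's event date is
#'   planted before the drug start (excluded by the onset analysis).
#' @param n_noncovid extra reports without the indication of interest.
#' @param multi_pt_prob probability a matched case reports a second
#'   matching preferred term of the same SMQ.
#' @param outcome_probs list of named probability vectors (`event`,
#'   `no_event`) over DE/LT/HO/DS/CA/RI/OT/none.
#' @param multi_outcome_prob probability a case with a serious outcome
#'   reports an additional, less serious outcome row.
#' @param onset_dist list: `name` ("exponential") plus `mean_exposed`,
#'   `mean_control`, mean days from drug start to event onset.
#' @param n_events_exposed,n_events_control optional exact event counts
#'   per arm (override the probabilistic draw).
#' @param covid_pts,aki_pts preferred-term pools used to label indications
#'   and events (defaults: the bundled synthetic narrow lists).
#' @param seed integer RNG seed; generation is bit-reproducible given it.
#' @return a validated `scenario_config`.
#' @export
scenario_config <- function(n_exposed, n_control, true_or = 1,
                            baseline_event_prob = 0.05,
                            confounders = default_confounders(),
                            dup_version_prob = 0, partial_date_prob = 0,
                            preexisting_event_prob = 0,
                            negative_interval_prob = 0,
                            n_noncovid = 0, multi_pt_prob = 0.2,
                            outcome_probs = .default_outcome_probs(),
                            multi_outcome_prob = 0.1,
                            onset_dist = list(name = "exponential",
                                              mean_exposed = 4.91,
                                              mean_control = 3.03),
                            n_events_exposed = NULL,
                            n_events_control = NULL,
                            covid_pts = .bundled_pts("covid19"),
                            aki_pts = .bundled_pts("aki"),
                            seed = 1L) {
  if (n_exposed <= 0 || n_control <= 0) stop("case counts must be positive")
  if (!(baseline_event_prob > 0 && baseline_event_prob < 1)) {
    stop("baseline_event_prob must be in (0,1)")
  }
  if (!(true_or > 0) || !is.finite(true_or)) {
    stop("true_or must be positive and finite")
  }
  p_exposed <- plogis(log(true_or) + qlogis(baseline_event_prob))
  if (!(p_exposed > 0 && p_exposed < 1)) {
    stop("derived exposed-arm event probability is outside (0,1)")
  }
  if (!all(c("age_band", "sex", "reporter", "country") %in%
             names(confounders))) {
    stop("confounders must cover age_band, sex, reporter and country")
  }
  probs <- c(dup_version_prob, partial_date_prob, preexisting_event_prob,
             negative_interval_prob, multi_pt_prob, multi_outcome_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  for (nm in names(confounders)) {
    cf <- confounders[[nm]]
    for (p in list(cf$prob_exposed, cf$prob_control)) {
      if (length(p) != length(cf$levels) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-6) {
        stop("confounder '", nm,
             "': level probabilities must be a distribution over its levels")
      }
    }
  }
  for (arm in c("event", "no_event")) {
    p <- outcome_probs[[arm]]
    if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
      stop("outcome_probs$", arm, " must be a probability distribution")
    }
  }
  structure(list(
    n_exposed = as.integer(n_exposed), n_control = as.integer(n_control),
    true_or = true_or, baseline_event_prob = baseline_event_prob,
    p_event_exposed = p_exposed, confounders = confounders,
    dup_version_prob = dup_version_prob,
    partial_date_prob = partial_date_prob,
    preexisting_event_prob = preexisting_event_prob,
    negative_interval_prob = negative_interval_prob,
    n_noncovid = as.integer(n_noncovid), multi_pt_prob = multi_pt_prob,
    outcome_probs = outcome_probs, multi_outcome_prob = multi_outcome_prob,
    onset_dist = onset_dist,
    n_events_exposed = n_events_exposed,
    n_events_control = n_events_control,
    covid_pts = covid_pts, aki_pts = aki_pts,
    seed = as.integer(seed)), class = "scenario_config")
}

# solve intercept a s.t. mean(plogis(a + eta)) == target
.calibrate_intercept <- function(eta, target) {
  if (all(eta == 0)) return(qlogis(target))
  stats::uniroot(function(a) mean(plogis(a + eta)) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

#' Generate a synthetic FAERS quarter with ground truth
#'
#' @param config a [scenario_config()].
#' @return a `faers_scenario`: list with `tables` (named list `demo`,
#'   `drug`, `reac`, `outc`, `rpsr`, `ther`, `indi`, each readable and
#'   writable by the `faers_io` functions) and `truth`, the ground-truth
#'   ledger (`cases` data.frame with every planted per-case label, the
#'   planted post-exclusion 2x2 `table` as `c(a, b, c, d)`, realized group
#'   sizes and bookkeeping counts).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, .generate_impl(config))
}

.generate_impl <- function(cfg) {
  nE <- cfg$n_exposed; nC <- cfg$n_control
  n <- nE + nC
  cfn <- cfg$confounders
  exp_beta_on <- any(vapply(cfn, function(x) any(x$exposure_logodds != 0),
                            logical(1)))

  if (exp_beta_on) {
    # covariates first (control-arm distribution), exposure from a logistic
    # model calibrated so the expected exposed count is n_exposed
    cov <- lapply(cfn, function(x) {
      sample(x$levels, n, replace = TRUE, prob = x$prob_control)
    })
    eta <- rowSums(vapply(names(cfn), function(nm) {
      unname(cfn[[nm]]$exposure_logodds[cov[[nm]]])
    }, numeric(n)))
    alpha <- .calibrate_intercept(eta, nE / n)
    exposed <- runif(n) < plogis(alpha + eta)
  } else {
    exposed <- rep(FALSE, n)
    exposed[sample.int(n, nE)] <- TRUE
    cov <- lapply(cfn, function(x) {
      out <- character(n)
      out[exposed] <- sample(x$levels, sum(exposed), replace = TRUE,
                             prob = x$prob_exposed)
      out[!exposed] <- sample(x$levels, sum(!exposed), replace = TRUE,
                              prob = x$prob_control)
      out
    })
  }

  # event assignment: arm-level targets, covariate effects calibrated out
  eta_ev <- rowSums(vapply(names(cfn), function(nm) {
    unname(cfn[[nm]]$event_logodds[cov[[nm]]])
  }, numeric(n)))
  event <- logical(n)
  for (arm in c(TRUE, FALSE)) {
    idx <- which(exposed == arm)
    target <- if (arm) cfg$p_event_exposed else cfg$baseline_event_prob
    k_exact <- if (arm) cfg$n_events_exposed else cfg$n_events_control
    if (!is.null(k_exact)) {
      event[sample(idx, k_exact)] <- TRUE
    } else {
      a <- .calibrate_intercept(eta_ev[idx], target)
      event[idx] <- runif(length(idx)) < plogis(a + eta_ev[idx])
    }
  }

  preexisting <- runif(n) < cfg$preexisting_event_prob

  caseid <- as.character(10000000L + seq_len(n + cfg$n_noncovid))
  primaryid <- paste0(caseid, "2")
  pid <- primaryid[seq_len(n)]

  # dates ----------------------------------------------------------------
  d0 <- as.Date("2020-03-01")
  start_date <- d0 + sample.int(250L, n, replace = TRUE)
  fda_dt <- format(start_date + sample.int(60L, n, replace = TRUE),
                   "%Y%m%d")
  onset <- rep(NA_integer_, n)
  mean_onset <- ifelse(exposed, cfg$onset_dist$mean_exposed,
                       cfg$onset_dist$mean_control)
  ev_i <- which(event)
  # rounding to whole days keeps the expected value at the target mean
  # (E[round(X)] for exponential X differs from E[X] only in the 3rd digit)
  onset[ev_i] <- as.integer(round(rexp(length(ev_i),
                                       rate = 1 / mean_onset[ev_i])))
  neg <- event & runif(n) < cfg$negative_interval_prob
  onset[neg] <- -sample.int(5L, sum(neg), replace = TRUE)
  event_date <- rep(as.Date(NA), n)
  event_date[ev_i] <- start_date[ev_i] + onset[ev_i]
  non_ev <- which(!event)
  event_date[non_ev] <- start_date[non_ev] +
    sample.int(15L, length(non_ev), replace = TRUE)
  event_dt <- format(event_date, "%Y%m%d")
  event_dt[!event & runif(n) < 0.2] <- ""
  start_dt <- format(start_date, "%Y%m%d")
  ev_partial <- nzchar(event_dt) & runif(n) < cfg$partial_date_prob
  event_dt[ev_partial] <- substr(event_dt[ev_partial], 1L, 6L)
  st_partial <- runif(n) < cfg$partial_date_prob / 2
  start_dt[st_partial] <- substr(start_dt[st_partial], 1L, 6L)

  # demographics ---------------------------------------------------------
  band <- cov$age_band
  age <- character(n); age_cod <- character(n)
  rng <- list("<18" = 1:17, "18-44" = 18:44, "45-64" = 45:64,
              ">=65" = 65:95)
  for (b in names(rng)) {
    i <- which(band == b)
    age[i] <- as.character(sample(rng[[b]], length(i), replace = TRUE))
    age_cod[i] <- "YR"
  }
  kid <- which(band == "<18" & runif(n) < 0.3)
  age[kid] <- as.character(as.integer(age[kid]) * 12L)
  age_cod[kid] <- "MON"
  sex <- ifelse(cov$sex == "Unknown", "", cov$sex)
  occp <- character(n)
  hp <- cov$reporter == "Health professional"
  occp[hp] <- sample(c("MD", "PH", "OT"), sum(hp), replace = TRUE)
  occp[cov$reporter == "Non-health professional"] <- "CN"
  country <- cov$country

  demo <- data.frame(
    primaryid = pid, caseid = caseid[seq_len(n)], fda_dt = fda_dt,
    event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
    occp_cod = occp, occr_country = country, stringsAsFactors = FALSE)

  # child tables ---------------------------------------------------------
  drugname <- character(n); prod_ai <- character(n)
  drugname[exposed] <- sample(c("REMDESIVIR", "VEKLURY", "REMDESIVIR 100MG"),
                              sum(exposed), replace = TRUE)
  prod_ai[exposed] <- "REMDESIVIR"
  ctrl_drug <- sample(.control_drug_pool, sum(!exposed), replace = TRUE)
  drugname[!exposed] <- ctrl_drug
  prod_ai[!exposed] <- ctrl_drug
  drug <- data.frame(primaryid = pid, drug_seq = "1", role_cod = "PS",
                     drugname = drugname, prod_ai = prod_ai,
                     stringsAsFactors = FALSE)
  conc <- runif(n) < 0.15
  rem_conc <- !exposed & runif(n) < 0.03   # role restriction exercise
  drug <- rbind(
    drug,
    data.frame(primaryid = pid[conc], drug_seq = "2", role_cod = "C",
               drugname = "PARACETAMOL", prod_ai = "PARACETAMOL",
               stringsAsFactors = FALSE),
    data.frame(primaryid = pid[rem_conc], drug_seq = "3", role_cod = "C",
               drugname = "REMDESIVIR", prod_ai = "REMDESIVIR",
               stringsAsFactors = FALSE))

  aki_pt1 <- sample(cfg$aki_pts, n, replace = TRUE)
  reac <- data.frame(primaryid = pid,
                     pt = sample(.generic_pts, n, replace = TRUE),
                     stringsAsFactors = FALSE)
  reac <- rbind(reac,
                data.frame(primaryid = pid[event], pt = aki_pt1[event],
                           stringsAsFactors = FALSE))
  multi_ev <- event & runif(n) < cfg$multi_pt_prob &
    length(cfg$aki_pts) > 1L
  if (any(multi_ev)) {
    second <- vapply(which(multi_ev), function(i) {
      sample(setdiff(cfg$aki_pts, aki_pt1[i]), 1L)
    }, character(1))
    reac <- rbind(reac, data.frame(primaryid = pid[multi_ev], pt = second,
                                   stringsAsFactors = FALSE))
  }

  covid_pt1 <- sample(cfg$covid_pts, n, replace = TRUE)
  indi <- data.frame(primaryid = pid, indi_drug_seq = "1",
                     indi_pt = covid_pt1, stringsAsFactors = FALSE)
  multi_cv <- runif(n) < cfg$multi_pt_prob & length(cfg$covid_pts) > 1L
  if (any(multi_cv)) {
    second <- vapply(which(multi_cv), function(i) {
      sample(setdiff(cfg$covid_pts, covid_pt1[i]), 1L)
    }, character(1))
    indi <- rbind(indi, data.frame(primaryid = pid[multi_cv],
                                   indi_drug_seq = "1", indi_pt = second,
                                   stringsAsFactors = FALSE))
  }
  if (any(preexisting)) {
    indi <- rbind(indi, data.frame(
      primaryid = pid[preexisting], indi_drug_seq = "1",
      indi_pt = sample(cfg$aki_pts, sum(preexisting), replace = TRUE),
      stringsAsFactors = FALSE))
  }

  oc_codes <- names(cfg$outcome_probs$event)
  outcome <- character(n)
  outcome[event] <- sample(oc_codes, sum(event), replace = TRUE,
                           prob = cfg$outcome_probs$event)
  outcome[!event] <- sample(oc_codes, sum(!event), replace = TRUE,
                            prob = cfg$outcome_probs$no_event)
  has_oc <- outcome != "none"
  outc <- data.frame(primaryid = pid[has_oc], outc_cod = outcome[has_oc],
                     stringsAsFactors = FALSE)
  extra_i <- which(has_oc & outcome != "OT" &
                     runif(n) < cfg$multi_outcome_prob)
  if (length(extra_i) > 0L) {
    lesser <- vapply(extra_i, function(i) {
      r <- match(outcome[i], outcome_severity)
      sample(outcome_severity[(r + 1L):7L], 1L)
    }, character(1))
    outc <- rbind(outc, data.frame(primaryid = pid[extra_i],
                                   outc_cod = lesser,
                                   stringsAsFactors = FALSE))
  }

  ther <- data.frame(primaryid = pid, dsg_drug_seq = "1",
                     start_dt = start_dt, stringsAsFactors = FALSE)
  late <- runif(n) < 0.1
  if (any(late)) {
    late_dt <- format(start_date[late] +
                        sample.int(10L, sum(late), replace = TRUE) + 2L,
                      "%Y%m%d")
    # partial-date truncation applies to all of a case's therapy rows
    trunc <- st_partial[late]
    late_dt[trunc] <- substr(late_dt[trunc], 1L, 6L)
    ther <- rbind(ther, data.frame(
      primaryid = pid[late], dsg_drug_seq = "1", start_dt = late_dt,
      stringsAsFactors = FALSE))
  }
  rpsr <- data.frame(primaryid = pid,
                     rpsr_cod = sample(c("FGN", "HP", "CSM"), n,
                                       replace = TRUE),
                     stringsAsFactors = FALSE)

  # non-indication noise reports -----------------------------------------
  if (cfg$n_noncovid > 0L) {
    m <- cfg$n_noncovid
    i <- n + seq_len(m)
    npid <- primaryid[i]
    ndemo <- data.frame(
      primaryid = npid, caseid = caseid[i],
      fda_dt = format(d0 + sample.int(300L, m, replace = TRUE), "%Y%m%d"),
      event_dt = "", age = as.character(sample(20:90, m, replace = TRUE)),
      age_cod = "YR", sex = sample(c("F", "M"), m, replace = TRUE),
      occp_cod = "MD",
      occr_country = sample(c("US", "FR"), m, replace = TRUE),
      stringsAsFactors = FALSE)
    demo <- rbind(demo, ndemo)
    ndrug_name <- sample(c("REMDESIVIR", .control_drug_pool), m,
                         replace = TRUE)
    drug <- rbind(drug, data.frame(
      primaryid = npid, drug_seq = "1", role_cod = "PS",
      drugname = ndrug_name, prod_ai = ndrug_name,
      stringsAsFactors = FALSE))
    reac <- rbind(reac, data.frame(
      primaryid = npid,
      pt = sample(c(.generic_pts, cfg$aki_pts), m, replace = TRUE),
      stringsAsFactors = FALSE))
    indi <- rbind(indi, data.frame(
      primaryid = npid, indi_drug_seq = "1",
      indi_pt = sample(.noncovid_indications, m, replace = TRUE),
      stringsAsFactors = FALSE))
  }

  # duplicate report versions -------------------------------------------
  dup_type <- rep("none", n)
  is_dup <- runif(n) < cfg$dup_version_prob
  dup_type[is_dup] <- sample(c("exact", "earlier_fda", "same_fda"),
                             sum(is_dup), replace = TRUE)
  exact_i <- which(dup_type == "exact")
  demo_exact <- demo[match(pid[exact_i], demo$primaryid), , drop = FALSE]
  ver_i <- which(dup_type %in% c("earlier_fda", "same_fda"))
  if (length(ver_i) > 0L) {
    old <- demo[match(pid[ver_i], demo$primaryid), , drop = FALSE]
    old$primaryid <- paste0(caseid[ver_i], "1")
    earlier <- dup_type[ver_i] == "earlier_fda"
    old$fda_dt[earlier] <- format(
      as.Date(old$fda_dt[earlier], "%Y%m%d") -
        sample.int(40L, sum(earlier), replace = TRUE), "%Y%m%d")
    demo <- rbind(demo, old)
    # the superseded versions carry their own child rows
    clone <- function(tb) {
      keep <- tb[as.character(tb$primaryid) %in% pid[ver_i], , drop = FALSE]
      keep$primaryid <- paste0(
        substr(keep$primaryid, 1L, nchar(keep$primaryid) - 1L), "1")
      rbind(tb, keep)
    }
    drug <- clone(drug); reac <- clone(reac); indi <- clone(indi)
    outc <- clone(outc); ther <- clone(ther); rpsr <- clone(rpsr)
  }
  if (length(exact_i) > 0L) demo <- rbind(demo, demo_exact)

  shuffle <- function(tb) tb[sample.int(nrow(tb)), , drop = FALSE]
  tables <- lapply(list(demo = demo, drug = drug, reac = reac, outc = outc,
                        rpsr = rpsr, ther = ther, indi = indi), shuffle)
  tables <- Map(function(tb, kind) {
    rownames(tb) <- NULL
    attr(tb, "table_kind") <- kind
    tb
  }, tables, c("DEMO", "DRUG", "REAC", "OUTC", "RPSR", "THER", "INDI"))

  in_tab <- !preexisting
  truth <- list(
    cases = data.frame(
      caseid = caseid[seq_len(n)], primaryid = pid,
      exposure = ifelse(exposed, "remdesivir", "control"),
      event = event, preexisting = preexisting,
      age_band = band, sex = cov$sex, reporter = cov$reporter,
      country = country, outcome = outcome, onset_days = onset,
      onset_observable = event & !neg & !ev_partial & !st_partial,
      stringsAsFactors = FALSE),
    table = c(a = sum(exposed & event & in_tab),
              b = sum(exposed & !event & in_tab),
              c = sum(!exposed & event & in_tab),
              d = sum(!exposed & !event & in_tab)),
    n_cases = n, n_exposed = sum(exposed), n_control = sum(!exposed),
    n_preexisting = sum(preexisting),
    n_noncovid = cfg$n_noncovid,
    n_exact_duplicates = length(exact_i),
    n_extra_versions = length(ver_i))
  structure(list(tables = tables, truth = truth, config = cfg),
            class = "faers_scenario")
}

#' @export
print.faers_scenario <- function(x, ...) {
  t <- x$truth
  cat(sprintf(paste0("synthetic FAERS scenario: %d cases ",
                     "(%d exposed / %d control), 2x2 = [%s]\n"),
              t$n_cases, t$n_exposed, t$n_control,
              paste(t$table, collapse = ", ")))
  invisible(x)
}

#' Bundled scenario calibrated to the reported cohort scale
#'
#' Group sizes 3,991 / 8,878 with control-arm event probability 516/8,878
#' and a target odds ratio of (589 x 8362) / (3402 x 516), so the expected
#' post-exclusion 2x2 table matches the reported crude table margins.
#' Demographic confounding, duplicate versions, partial dates and
#' pre-existing-condition reports are switched on at realistic rates.
#'
#' @param seed RNG seed.
#' @return a [scenario_config()].
#' @export
paper_scale_scenario <- function(seed = 1L) {
  cf <- default_confounders()
  cf$age_band$event_logodds[] <- c(0, 0.3, 0.8, 1.2, 0.5)
  cf$sex$event_logodds[] <- c(0, 0.4, 0.2)
  scenario_config(
    n_exposed = 3991L, n_control = 8878L,
    true_or = (589 * 8362) / (3402 * 516),
    baseline_event_prob = 516 / 8878,
    confounders = cf,
    dup_version_prob = 0.05, partial_date_prob = 0.25,
    preexisting_event_prob = 19 / 12888,
    negative_interval_prob = 0.03, n_noncovid = 300L,
    seed = seed)
}

#' Bundled null scenario (no association, no confounding)
#'
#' @param seed RNG seed.
#' @return a [scenario_config()] with `true_or = 1`.
#' @export
null_scenario <- function(seed = 1L) {
  scenario_config(n_exposed = 10000L, n_control = 10000L, true_or = 1,
                  baseline_event_prob = 0.05,
                  confounders = no_confounding(), seed = seed)
}

#' Write a generated scenario to FAERS-format files
#'
#' @param scenario a `faers_scenario`.
#' @param dir output directory (created if needed); files are named
#'   `DEMO.txt`, `DRUG.txt`, etc.
#' @return named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "faers_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(scenario$tables), function(nm) {
    p <- file.path(dir, paste0(toupper(nm), ".txt"))
    write_faers_table(scenario$tables[[nm]], p, toupper(nm))
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of FAERS-format files
#'
#' @param dir directory holding `DEMO.txt` ... `INDI.txt`.
#' @return named list of tables in the layout [generate_scenario()] uses.
#' @export
read_scenario_dir <- function(dir) {
  kinds <- faers_table_kinds
  tabs <- lapply(kinds, function(k) {
    read_faers_table(file.path(dir, paste0(k, ".txt")), k)
  })
  names(tabs) <- tolower(kinds)
  tabs
}
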