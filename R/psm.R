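#' @title Propensity-score estimation and 1:1 optimal caliper matching
#' @name psm
#' @description
#' Spontaneous-report groups differ systematically in the demographics
#' FAERS records (age, sex, reporter type, occurrence country), which
#' confounds crude disproportionality. The propensity score — the modelled
#' probability of being in the exposed group given those covariates — is
#' estimated by main-effects logistic regression with every missing value
#' kept as an explicit "Unknown" level (never imputed). Exposed and control
#' reports are then paired 1:1 without replacement: first exact pairing of
#' reports agreeing on all covariate levels, then optimal matching of the
#' remainder on propensity-score distance under a caliper (matching
#' tolerance) of 0.001.
NULL

#' Estimate propensity scores by main-effects logistic regression
#'
#' @param cohort cohort data.frame (see [build_cohort()]) with an
#'   `exposure` column and the covariate columns.
#' @param covariates covariate column names; each is treated as categorical
#'   with levels ordered by [covariate_levels()] (reference = first level,
#'   "Unknown" last).
#' @return named numeric vector of scores in (0,1), names = `caseid`;
#'   attribute `model` carries the fitted [stats::glm] object.
#' @export
estimate_propensity <- function(cohort,
                                covariates = c("age_band", "sex",
                                               "reporter", "country")) {
  stopifnot(all(covariates %in% names(cohort)))
  dat <- data.frame(
    .treat = as.integer(cohort$exposure == "remdesivir"),
    lapply(setNames(covariates, covariates), function(cv) {
      factor(cohort[[cv]], levels = covariate_levels(cohort[[cv]], cv))
    }),
    check.names = FALSE
  )
  dat[covariates] <- lapply(dat[covariates], droplevels)
  form <- as.formula(paste(".treat ~",
                           paste(sprintf("`%s`", covariates),
                                 collapse = " + ")))
  fit <- glm(form, family = binomial(), data = dat)
  scores <- as.numeric(predict(fit, type = "response"))
  names(scores) <- as.character(cohort$caseid)
  attr(scores, "model") <- fit
  scores
}

# deterministic ordering: score, then numeric caseid
.score_order <- function(scores, ids) {
  order(scores[ids], .id_order_key(ids), method = "radix")
}

#' 1:1 optimal matching within a propensity-score caliper
#'
#' Stage 1 (when `exact_data` is given): reports agreeing on every
#' covariate level are paired directly, in caseid order within each
#' stratum. Stage 2: the remaining reports are matched by the exact optimal
#' caliper matcher, which maximises the number of pairs admissible under
#' the caliper and, among those pairings, minimises the total within-pair
#' score distance. Matching is without replacement; unmatched exposed
#' reports are dropped from the matched analysis. Ties are broken by lower
#' caseid, so the procedure is fully deterministic.
#'
#' @param scores named score vector from [estimate_propensity()].
#' @param exposed_ids,control_ids caseids of the two groups.
#' @param caliper maximum within-pair score distance (default 0.001).
#' @param exact_data optional data.frame (caseid-keyed, column `caseid`)
#'   holding the covariate columns used for the exact stage.
#' @param covariates covariate columns of `exact_data` used for exact
#'   agreement.
#' @return a `match_result`: `pairs` (data.frame `exposed`, `control`,
#'   `distance`, `method`), `n_matched`, `n_exposed`, `n_control`,
#'   `scores`. Empty `pairs` with a warning when no admissible pair exists.
#' @export
match_pairs <- function(scores, exposed_ids, control_ids, caliper = 0.001,
                        exact_data = NULL,
                        covariates = c("age_band", "sex", "reporter",
                                       "country")) {
  if (caliper <= 0) stop("caliper must be positive")
  exposed_ids <- as.character(exposed_ids)
  control_ids <- as.character(control_ids)
  stopifnot(all(c(exposed_ids, control_ids) %in% names(scores)))
  n_exp0 <- length(exposed_ids)
  n_con0 <- length(control_ids)

  pairs <- list()
  if (!is.null(exact_data)) {
    covariates <- intersect(covariates, names(exact_data))
    key <- do.call(paste, c(exact_data[covariates], sep = "\r"))
    names(key) <- as.character(exact_data$caseid)
    for (stratum in intersect(unique(key[exposed_ids]),
                              unique(key[control_ids]))) {
      es <- exposed_ids[key[exposed_ids] == stratum]
      cs <- control_ids[key[control_ids] == stratum]
      es <- es[order(.id_order_key(es))]
      cs <- cs[order(.id_order_key(cs))]
      k <- min(length(es), length(cs))
      if (k == 0L) next
      d <- abs(scores[es[seq_len(k)]] - scores[cs[seq_len(k)]])
      ok <- d <= caliper
      if (!any(ok)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        exposed = es[seq_len(k)][ok], control = cs[seq_len(k)][ok],
        distance = unname(d[ok]), method = "exact",
        stringsAsFactors = FALSE)
      exposed_ids <- setdiff(exposed_ids, es[seq_len(k)][ok])
      control_ids <- setdiff(control_ids, cs[seq_len(k)][ok])
    }
  }

  if (length(exposed_ids) > 0L && length(control_ids) > 0L) {
    eo <- exposed_ids[.score_order(scores, exposed_ids)]
    co <- control_ids[.score_order(scores, control_ids)]
    m <- caliper_match_dp(unname(scores[eo]), unname(scores[co]), caliper)
    hit <- m > 0L
    if (any(hit)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        exposed = eo[hit], control = co[m[hit]],
        distance = abs(unname(scores[eo[hit]] - scores[co[m[hit]]])),
        method = "fuzzy", stringsAsFactors = FALSE)
    }
  }

  pairs <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(exposed = character(0), control = character(0),
               distance = numeric(0), method = character(0),
               stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    warning("no admissible pair within the caliper; matched set is empty")
  }
  structure(list(pairs = pairs, n_matched = nrow(pairs),
                 n_exposed = n_exp0, n_control = n_con0,
                 scores = scores), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("1:1 matched set: %d pairs (%d exact, %d fuzzy)\n",
              x$n_matched, sum(x$pairs$method == "exact"),
              sum(x$pairs$method == "fuzzy")))
  invisible(x)
}

#' Estimate scores and match a cohort in one step
#'
#' @inheritParams estimate_propensity
#' @param caliper matching tolerance on the propensity-score scale.
#' @param exact_then_fuzzy pair covariate-identical reports first.
#' @return the `match_result`, plus a `matched_cohort` element: the cohort
#'   rows of the matched reports.
#' @export
psm_match <- function(cohort,
                      covariates = c("age_band", "sex", "reporter",
                                     "country"),
                      caliper = 0.001, exact_then_fuzzy = TRUE) {
  scores <- estimate_propensity(cohort, covariates)
  res <- match_pairs(
    scores,
    cohort$caseid[cohort$exposure == "remdesivir"],
    cohort$caseid[cohort$exposure == "control"],
    caliper = caliper,
    exact_data = if (exact_then_fuzzy) cohort[c("caseid", covariates)],
    covariates = covariates)
  res$matched_cohort <- cohort[cohort$caseid %in%
                                 c(res$pairs$exposed, res$pairs$control), ,
                               drop = FALSE]
  res
}

#' Covariate balance table with chi-square tests and standardised differences
#'
#' Reproduces the characteristics-table layout: per covariate level, counts
#' and column percentages per group, plus a Pearson r x c chi-square across
#' levels and the maximum absolute standardised difference over levels.
#'
#' @param cohort full cohort data.frame.
#' @param covariates covariate columns to tabulate.
#' @param match_result optional `match_result`; when given, the table is
#'   computed on the matched reports only.
#' @return list with `levels` (covariate, level, n/% per group) and `tests`
#'   (covariate, chi2, df, p, std_diff_max).
#' @export
balance_table <- function(cohort,
                          covariates = c("age_band", "sex", "reporter",
                                         "country"),
                          match_result = NULL) {
  if (!is.null(match_result)) {
    cohort <- cohort[cohort$caseid %in% c(match_result$pairs$exposed,
                                          match_result$pairs$control), ,
                     drop = FALSE]
  }
  grp <- cohort$exposure == "remdesivir"
  lev_rows <- list(); test_rows <- list()
  for (cv in covariates) {
    lv <- covariate_levels(cohort[[cv]], cv)
    f <- factor(cohort[[cv]], levels = lv)
    tab <- table(f, factor(ifelse(grp, "remdesivir", "control"),
                           levels = c("remdesivir", "control")))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    p1 <- tab[, 1] / max(1, sum(tab[, 1]))
    p2 <- tab[, 2] / max(1, sum(tab[, 2]))
    sd_pool <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    std <- ifelse(sd_pool > 0, abs(p1 - p2) / sd_pool, 0)
    ct <- pearson_rxc(tab)
    lev_rows[[cv]] <- data.frame(
      covariate = cv, level = rownames(tab),
      n_exposed = as.integer(tab[, 1]), pct_exposed = 100 * as.numeric(p1),
      n_control = as.integer(tab[, 2]), pct_control = 100 * as.numeric(p2),
      stringsAsFactors = FALSE)
    test_rows[[cv]] <- data.frame(
      covariate = cv, chi2 = ct$statistic, df = ct$df, p = ct$p,
      std_diff_max = max(std), stringsAsFactors = FALSE)
  }
  list(levels = do.call(rbind, c(lev_rows, make.row.names = FALSE)),
       tests = do.call(rbind, c(test_rows, make.row.names = FALSE)))
}
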