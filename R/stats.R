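#' @title Contingency-table statistics for signal detection
#' @name disprop
#' @description
#' The reporting odds ratio (ROR) compares the odds of the event of interest
#' among reports for the index drug against the odds among reports for the
#' comparator drugs. On the 2x2 table with a = index & event, b = index &
#' no event, c = comparator & event, d = comparator & no event:
#' ROR = (a d)/(b c), with the Woolf (log-odds) 95% interval
#' exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). A disproportionality
#' signal is flagged when the lower 95% bound exceeds 1. The accompanying
#' Pearson chi-square is uncorrected (no Yates continuity correction).
NULL

#' Reporting odds ratio with Woolf confidence interval
#'
#' @param a,b,c,d non-negative integer counts: exposed+event, exposed+no
#'   event, control+event, control+no event.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return a `contingency_result`: counts, `ror`, `ci_low`, `ci_high`,
#'   `chi2` (uncorrected Pearson), `p`, `test_used` ("chi-square" unless any
#'   expected count is below 5, then Fisher), `signal` (`ci_low > 1`) and
#'   `degenerate` (TRUE when a zero cell forced the Haldane-Anscombe +0.5
#'   correction; the interval is then marked, not suppressed).
#' @examples
#' ror_2x2(589, 3402, 516, 8362)  # ROR 2.81, CI (2.48, 3.18), chi2 280.73
#' @export
ror_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  counts <- c(a = a, b = b, c = c, d = d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  degenerate <- any(counts == 0)
  k <- if (degenerate) counts + 0.5 else counts
  ror <- (k[["a"]] * k[["d"]]) / (k[["b"]] * k[["c"]])
  se <- sqrt(sum(1 / k))
  ci <- exp(log(ror) + c(-1, 1) * z * se)

  n <- sum(counts)
  chi2 <- if (n > 0) {
    n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
  } else NA_real_
  test_used <- choose_test(matrix(counts, 2, 2, byrow = TRUE))
  p <- if (test_used == "fisher") fisher_2x2(a, b, c, d)
       else pchisq(chi2, df = 1, lower.tail = FALSE)

  structure(list(a = a, b = b, c = c, d = d,
                 ror = unname(ror), ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level,
                 chi2 = unname(chi2), p = unname(p), test_used = test_used,
                 signal = unname(ci[1] > 1), degenerate = degenerate),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, digits = 2, ...) {
  cat(sprintf("2x2 table: a=%g b=%g c=%g d=%g\n", x$a, x$b, x$c, x$d))
  cat(sprintf("ROR %.2f, %d%% CI (%.2f, %.2f)%s\n", x$ror,
              round(100 * x$conf_level), x$ci_low, x$ci_high,
              if (x$degenerate) " [zero cell: +0.5 correction]" else ""))
  cat(sprintf("Pearson chi2 %.2f, p %s (%s)%s\n", x$chi2,
              format(signif(x$p, 3)), x$test_used,
              if (x$signal) " -- SIGNAL (lower CI bound > 1)" else ""))
  invisible(x)
}

#' Uncorrected Pearson chi-square for an r x c table
#'
#' @param table matrix of non-negative counts.
#' @return list with `statistic` = sum (O-E)^2/E, `df` = (r-1)(c-1), `p`.
#' @export
pearson_rxc <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  cells <- expected > 0
  stat <- sum((table[cells] - expected[cells])^2 / expected[cells])
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE),
       expected = expected)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by summation of the hypergeometric probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed table (with the customary 1 + 1e-7 relative tolerance at the
#' boundary).
#'
#' @param a,b,c,d non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Select chi-square or Fisher for a contingency table
#'
#' Pearson's chi-square when every expected count is at least 5, Fisher's
#' exact test otherwise (sparse tables).
#'
#' @param table matrix of counts.
#' @return "chi-square" or "fisher".
#' @export
choose_test <- function(table) {
  table <- as.matrix(table)
  n <- sum(table)
  if (n == 0) return("fisher")
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected < 5)) "fisher" else "chi-square"
}

#' Build the drug x event 2x2 table from a cohort and compute the ROR
#'
#' @param cohort a cohort data.frame with `exposure` ("remdesivir"/"control")
#'   and logical `event` columns, as produced by [build_cohort()].
#' @return a `contingency_result`.
#' @export
cohort_ror <- function(cohort) {
  e <- cohort$exposure == "remdesivir"
  ror_2x2(sum(e & cohort$event), sum(e & !cohort$event),
          sum(!e & cohort$event), sum(!e & !cohort$event))
}
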