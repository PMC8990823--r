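#' @title FDA-recommended case deduplication
#' @name dedup
#' @description
#' A FAERS case accumulates report versions: the same CASEID appears under
#' several PRIMARYIDs as follow-up information arrives, and occasionally the
#' same row is shipped twice. The FDA-recommended reduction keeps one record
#' per case: drop byte-identical DEMO rows, then keep the latest FDA_DT per
#' CASEID, then the highest PRIMARYID among records sharing that FDA_DT.
NULL

# right-pad partial yyyymmdd strings with zeros to 8 digits so that
# lexicographic comparison equals chronological comparison for valid dates
.pad_date8 <- function(x) {
  x <- gsub("[^0-9]", "", as.character(x))
  x[is.na(x)] <- ""
  n <- nchar(x)
  short <- n < 8L
  x[short] <- paste0(x[short], strrep("0", 8L - n[short]))
  substr(x, 1L, 8L)
}

# numeric order when every id parses as a number, else lexicographic
.id_order_key <- function(id) {
  num <- suppressWarnings(as.numeric(id))
  if (!anyNA(num)) num else xtfrm(as.character(id))
}

#' Deduplicate DEMO report versions to one record per case
#'
#' Applies, in order: (1) byte-identical rows collapse to one; (2) within a
#' CASEID only the maximal FDA_DT survives; (3) among those, only the maximal
#' PRIMARYID survives. Partial FDA_DT strings are right-padded with zeros
#' before comparison; PRIMARYID comparison is numeric when all ids parse as
#' numbers. Records with an empty CASEID cannot be grouped and are passed
#' through unchanged and flagged in the report.
#'
#' @param demo DEMO data.frame with `primaryid`, `caseid`, `fda_dt` columns.
#' @return list with `records` (the surviving rows, input order preserved)
#'   and `report`, a `dedup_report` with `input_count`,
#'   `exact_duplicates_removed`, `versions_collapsed`, `output_count` and
#'   `ungroupable` (count of empty-CASEID pass-through rows).
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  n_in <- nrow(demo)
  exact_dup <- duplicated(demo)
  d1 <- demo[!exact_dup, , drop = FALSE]
  n_exact <- sum(exact_dup)

  caseid <- as.character(d1$caseid)
  ungroupable <- is.na(caseid) | !nzchar(trimws(caseid))
  grp <- d1[!ungroupable, , drop = FALSE]

  keep <- logical(nrow(grp))
  if (nrow(grp) > 0L) {
    ord <- order(as.character(grp$caseid), .pad_date8(grp$fda_dt),
                 .id_order_key(grp$primaryid), method = "radix")
    last <- !duplicated(as.character(grp$caseid)[ord], fromLast = TRUE)
    keep[ord[last]] <- TRUE
  }
  n_versions <- sum(!keep)

  sel <- ungroupable
  sel[!ungroupable] <- keep
  survivors <- d1[sel, , drop = FALSE]

  report <- structure(list(
    input_count = n_in,
    exact_duplicates_removed = n_exact,
    versions_collapsed = n_versions,
    output_count = nrow(survivors),
    ungroupable = sum(ungroupable)
  ), class = "dedup_report")
  stopifnot(report$output_count ==
              report$input_count - report$exact_duplicates_removed -
              report$versions_collapsed)
  list(records = survivors, report = report)
}

#' @export
print.dedup_report <- function(x, ...) {
  cat("FAERS deduplication:", x$input_count, "rows ->", x$output_count,
      "cases (", x$exact_duplicates_removed, "exact duplicates,",
      x$versions_collapsed, "superseded versions removed;",
      x$ungroupable, "ungroupable )\n")
  invisible(x)
}

#' Restrict child tables to surviving report versions
#'
#' After deduplication the child tables (DRUG/REAC/OUTC/RPSR/THER/INDI) are
#' filtered to the surviving PRIMARYIDs; the reduction itself operates on
#' DEMO only.
#'
#' @param tables named list of FAERS tables (each with a `primaryid` column).
#' @param primaryids character vector of surviving ids.
#' @return the list with every table filtered.
#' @export
filter_to_cases <- function(tables, primaryids) {
  lapply(tables, function(tb) {
    if (is.null(tb) || !"primaryid" %in% names(tb)) return(tb)
    tb[as.character(tb$primaryid) %in% as.character(primaryids), ,
       drop = FALSE]
  })
}
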