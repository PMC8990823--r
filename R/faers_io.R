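#' @title FAERS quarterly-extract table I/O
#' @name faers_io
#' @description
#' The FAERS Quarterly Data Extract distributes each quarter as seven
#' "$"-delimited ASCII tables with one header line: DEMO (demographics),
#' DRUG, REAC (reactions as MedDRA preferred terms), OUTC (outcomes),
#' RPSR (report sources), THER (therapy dates) and INDI (indications).
#' These readers keep every field as character: FAERS dates are yyyymmdd
#' strings that may be partial, and their validity is resolved only at the
#' stage that needs it (deduplication, time-to-onset).
NULL

#' Recognised FAERS table kinds
#' @export
faers_table_kinds <- c("DEMO", "DRUG", "REAC", "OUTC", "RPSR", "THER", "INDI")

# mandatory columns per table kind (after header normalisation)
.faers_required <- list(
  DEMO = c("primaryid", "caseid"),
  DRUG = "primaryid", REAC = "primaryid", OUTC = "primaryid",
  RPSR = "primaryid", THER = "primaryid", INDI = "primaryid"
)

# legacy/alias header names mapped onto the canonical vocabulary
.faers_aliases <- c(gndr_cod = "sex", isr = "primaryid", "case" = "caseid")

.normalize_header <- function(h) {
  h <- tolower(trimws(h))
  hit <- h %in% names(.faers_aliases)
  h[hit] <- .faers_aliases[h[hit]]
  h
}

#' Read one FAERS quarterly-extract ASCII table
#'
#' Parses a "$"-delimited FAERS table. All fields are returned as character
#' columns; unknown columns are preserved as-is. Header names are matched
#' case-insensitively and a few legacy aliases (e.g. `GNDR_COD`) are mapped
#' to the current vocabulary. Lines whose field count does not match the
#' header are skipped and counted in the attached parse report.
#'
#' @param path path to the table file.
#' @param table_kind one of `faers_table_kinds`.
#' @return A `data.frame` of character columns with attributes
#'   `table_kind` and `parse_report` (a list with `data_lines`, `records`,
#'   `skipped`). `records + skipped == data_lines` always holds.
#' @export
read_faers_table <- function(path, table_kind) {
  table_kind <- match.arg(toupper(table_kind), faers_table_kinds)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file (no header line): ", path)
  header <- .normalize_header(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]])
  nf <- length(header)
  req <- .faers_required[[table_kind]]
  missing_col <- setdiff(req, header)
  if (length(missing_col) > 0L) {
    stop(sprintf("%s table %s is missing mandatory column(s): %s",
                 table_kind, path, paste(missing_col, collapse = ", ")))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  len <- lengths(parts)
  # strsplit drops a single trailing empty field: pad exactly those rows
  # (a line ending in the delimiter), so a genuinely short line still
  # counts as malformed
  pad <- len == nf - 1L & endsWith(body, "$")
  if (any(pad)) {
    parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
    len[pad] <- nf
  }
  ok <- len == nf
  n_skip <- sum(!ok)
  if (any(ok)) {
    mat <- matrix(unlist(parts[ok], use.names = FALSE),
                  ncol = nf, byrow = TRUE)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- header
  } else {
    df <- as.data.frame(setNames(rep(list(character(0)), nf), header),
                        stringsAsFactors = FALSE)
  }
  attr(df, "table_kind") <- table_kind
  attr(df, "parse_report") <- list(data_lines = length(body),
                                   records = nrow(df), skipped = n_skip)
  df
}

#' Write a FAERS-format table
#'
#' Inverse of [read_faers_table()]: writes a "$"-delimited file with one
#' header line. `NA` values are written as empty fields, so a read/write
#' round trip is loss-free on all-character tables.
#'
#' @param records data.frame of character columns.
#' @param path output path.
#' @param table_kind one of `faers_table_kinds`; defaults to the table's
#'   `table_kind` attribute.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(records, path,
                              table_kind = attr(records, "table_kind")) {
  if (is.null(table_kind)) stop("table_kind must be supplied")
  table_kind <- match.arg(toupper(table_kind), faers_table_kinds)
  cols <- lapply(records, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  lines <- c(paste(names(records), collapse = "$"),
             if (nrow(records) > 0L) do.call(paste, c(cols, sep = "$")))
  writeLines(lines, path)
  invisible(path)
}

#' Convert FAERS age values to years
#'
#' FAERS reports age as a number plus a unit code. `DEC` is decades, `YR`
#' years, `MON` months, `WK` weeks, `DY` days, `HR` hours. Unrecognised or
#' empty codes, and non-numeric ages, yield `NA`.
#'
#' @param age numeric or character vector of ages.
#' @param age_cod character vector of unit codes (recycled against `age`).
#' @return numeric vector of ages in years.
#' @examples
#' normalize_age(24, "MON")    # 2
#' normalize_age(730.5, "DY")  # 2
#' @export
normalize_age <- function(age, age_cod) {
  to_years <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                DY = 1 / 365.25, HR = 1 / 8765.82)
  age <- suppressWarnings(as.numeric(age))
  f <- to_years[toupper(trimws(as.character(age_cod)))]
  unname(age * f)
}

#' Band ages in years into the reporting age groups
#'
#' Bands are closed on the left: 18 falls in "18-44" and 65 in ">=65".
#' Missing ages map to the explicit "Unknown" level.
#'
#' @param years numeric vector of ages in years.
#' @return character vector over `<18`, `18-44`, `45-64`, `>=65`, `Unknown`.
#' @export
age_band <- function(years) {
  out <- as.character(cut(years, breaks = c(-Inf, 18, 45, 65, Inf),
                          right = FALSE,
                          labels = c("<18", "18-44", "45-64", ">=65")))
  out[is.na(out)] <- "Unknown"
  out
}

#' Canonical level orderings for the cohort covariates
#'
#' Used by the propensity model and balance tables so that reference levels
#' are stable and "Unknown" is always the last level.
#'
#' @param values character vector of observed levels.
#' @param covariate one of "age_band", "sex", "reporter", or anything else
#'   (sorted levels, Unknown last).
#' @return character vector of levels.
#' @export
covariate_levels <- function(values, covariate = "other") {
  fixed <- switch(covariate,
    age_band = c("<18", "18-44", "45-64", ">=65", "Unknown"),
    sex      = c("F", "M", "Unknown"),
    reporter = c("Health professional", "Non-health professional", "Unknown"),
    NULL)
  if (!is.null(fixed)) return(intersect(fixed, unique(c(values, fixed))))
  lv <- sort(setdiff(unique(values), "Unknown"))
  c(lv, "Unknown")
}
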