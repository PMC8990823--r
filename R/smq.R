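#' @title Standardised MedDRA Query (SMQ) case and event identification
#' @name smq
#' @description
#' Cases and events are identified by matching MedDRA preferred terms (PTs)
#' against SMQ term lists. An SMQ has a narrow scope (highly specific terms)
#' and a broad scope (narrow plus sensitive terms). Matching is exact on the
#' normalised term text (lower-cased, whitespace-trimmed): PTs are a
#' controlled vocabulary, so substring matching would over-capture. A case
#' reporting several matching PTs of the same SMQ counts once.
#'
#' The package bundles placeholder COVID-19 (narrow, 18 PTs) and acute
#' kidney injury (narrow 19 PTs, broad 52 PTs) lists under
#' `inst/extdata`, assembled from public SMQ descriptions and labelled
#' synthetic: MedDRA is licensed, so the production lists are supplied by
#' the user in the same CSV layout.
NULL

.normalize_pt <- function(x) tolower(trimws(as.character(x)))

#' Construct an SMQ query
#'
#' @param name label, e.g. "COVID-19" or "Acute kidney injury".
#' @param scope "narrow" or "broad".
#' @param terms character vector of preferred terms (normalised internally).
#' @return an `smq_query` object.
#' @export
smq_query <- function(name, scope = c("narrow", "broad"), terms) {
  scope <- match.arg(scope)
  terms <- unique(.normalize_pt(terms))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("SMQ '", name, "': terms must be non-empty")
  structure(list(name = name, scope = scope, terms = terms),
            class = "smq_query")
}

#' @export
print.smq_query <- function(x, ...) {
  cat(sprintf("SMQ query '%s' (%s scope, %d preferred terms)\n",
              x$name, x$scope, length(x$terms)))
  invisible(x)
}

#' Read an SMQ term list from disk
#'
#' Accepts either a CSV with columns (`smq_name`, `scope`, `pt`) — `scope`
#' marks each term's narrowest scope, so a broad query takes all rows and a
#' narrow query only the `scope == "narrow"` rows — or a plain-text file
#' with one PT per line (all terms assigned to `scope`).
#'
#' @param path file path.
#' @param name SMQ label; when the CSV has an `smq_name` column, rows are
#'   filtered to it. Defaults to the file name.
#' @param scope query scope to build, "narrow" or "broad".
#' @return an [smq_query()].
#' @export
read_smq <- function(path, name = NULL, scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  if (!file.exists(path)) stop("SMQ file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl(",", first, fixed = TRUE)) {
    df <- read.csv(path, colClasses = "character", strip.white = TRUE)
    names(df) <- tolower(names(df))
    if (!"pt" %in% names(df)) stop("SMQ CSV needs a 'pt' column: ", path)
    if (!is.null(name) && "smq_name" %in% names(df)) {
      df <- df[.normalize_pt(df$smq_name) == .normalize_pt(name), ,
               drop = FALSE]
    }
    if (scope == "narrow" && "scope" %in% names(df)) {
      df <- df[tolower(df$scope) == "narrow", , drop = FALSE]
    }
    terms <- df$pt
  } else {
    terms <- readLines(path, warn = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  smq_query(name, scope, terms)
}

#' Load one of the bundled synthetic SMQ term lists
#'
#' @param smq "covid19" or "aki".
#' @param scope "narrow" or "broad" (COVID-19 ships narrow only).
#' @return an [smq_query()].
#' @export
bundled_smq <- function(smq = c("covid19", "aki"),
                        scope = c("narrow", "broad")) {
  smq <- match.arg(smq)
  scope <- match.arg(scope)
  file <- switch(smq,
    covid19 = "smq_covid19_synthetic.csv",
    aki = "smq_acute_kidney_injury_synthetic.csv")
  name <- switch(smq, covid19 = "COVID-19", aki = "Acute kidney injury")
  path <- system.file("extdata", file, package = "faersvig", mustWork = TRUE)
  read_smq(path, name = name, scope = scope)
}

#' Identify cases whose preferred terms match an SMQ
#'
#' Works on REAC records (`pt` column) for events and INDI records
#' (`indi_pt` column) for indications. Multiple matching PTs of the same
#' case collapse to one: the result is a set of PRIMARYIDs.
#'
#' @param records data.frame with `primaryid` and a `pt` or `indi_pt` column.
#' @param query an [smq_query()].
#' @return character vector of unique matching primaryids.
#' @export
match_cases <- function(records, query) {
  stopifnot(inherits(query, "smq_query"))
  pt_col <- intersect(c("pt", "indi_pt"), names(records))[1L]
  if (is.na(pt_col)) stop("records need a 'pt' or 'indi_pt' column")
  hit <- .normalize_pt(records[[pt_col]]) %in% query$terms
  unique(as.character(records$primaryid[hit]))
}

#' Remove cases whose indications already include the event of interest
#'
#' A report listing the adverse event among its drug indications describes a
#' condition present before treatment; such cases are excluded from the
#' event analysis.
#'
#' @param case_ids candidate primaryids.
#' @param indi_records INDI table.
#' @param event_query the event SMQ.
#' @return the retained primaryids, with attribute `excluded` carrying the
#'   removed ids.
#' @export
exclude_preexisting <- function(case_ids, indi_records, event_query) {
  pre <- match_cases(indi_records, event_query)
  out <- setdiff(as.character(case_ids), pre)
  attr(out, "excluded") <- intersect(as.character(case_ids), pre)
  out
}
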