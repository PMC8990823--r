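# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles by a different route than
# the implementation under test.

# quick DEMO builder
make_demo <- function(primaryid, caseid, fda_dt, extra = NULL) {
  df <- data.frame(primaryid = as.character(primaryid),
                   caseid = as.character(caseid),
                   fda_dt = as.character(fda_dt),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra, stringsAsFactors = FALSE)
  df
}

# group by caseid, sort by (padded fda_dt, numeric primaryid), take the last
oracle_dedup_ids <- function(demo) {
  demo <- unique(demo)
  pad <- function(x) {
    x <- gsub("[^0-9]", "", as.character(x))
    paste0(x, strrep("0", pmax(0L, 8L - nchar(x))))
  }
  groupable <- nzchar(trimws(as.character(demo$caseid)))
  out <- as.character(demo$primaryid[!groupable])
  for (cid in unique(as.character(demo$caseid[groupable]))) {
    g <- demo[groupable & as.character(demo$caseid) == cid, , drop = FALSE]
    g <- g[pad(g$fda_dt) == max(pad(g$fda_dt)), , drop = FALSE]
    pn <- as.numeric(g$primaryid)
    g <- g[pn == max(pn), , drop = FALSE]
    out <- c(out, as.character(g$primaryid[nrow(g)]))
  }
  sort(out)
}

# exhaustive search over all injective caliper-respecting pairings:
# maximise pair count, then minimise total |x - y| distance
oracle_match <- function(x, y, caliper) {
  best <- list(count = -1L, dist = Inf)
  used <- logical(length(y))
  rec <- function(i, cnt, dst) {
    if (cnt + (length(x) - i + 1L) < best$count) return()
    if (i > length(x)) {
      if (cnt > best$count ||
          (cnt == best$count && dst < best$dist - 1e-12)) {
        best <<- list(count = cnt, dist = dst)
      }
      return()
    }
    for (j in seq_along(y)) {
      d <- abs(x[i] - y[j])
      if (!used[j] && d <= caliper) {
        used[j] <<- TRUE
        rec(i + 1L, cnt + 1L, dst + d)
        used[j] <<- FALSE
      }
    }
    rec(i + 1L, cnt, dst)
  }
  rec(1L, 0L, 0)
  best
}

# two-sided Fisher p by explicit enumeration with choose() arithmetic
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# tiny seven-table skeleton for hand-built fixtures
empty_tables <- function() {
  list(
    demo = data.frame(primaryid = character(0), caseid = character(0),
                      fda_dt = character(0), event_dt = character(0),
                      age = character(0), age_cod = character(0),
                      sex = character(0), occp_cod = character(0),
                      occr_country = character(0)),
    drug = data.frame(primaryid = character(0), drug_seq = character(0),
                      role_cod = character(0), drugname = character(0),
                      prod_ai = character(0)),
    reac = data.frame(primaryid = character(0), pt = character(0)),
    outc = data.frame(primaryid = character(0), outc_cod = character(0)),
    rpsr = data.frame(primaryid = character(0), rpsr_cod = character(0)),
    ther = data.frame(primaryid = character(0), dsg_drug_seq = character(0),
                      start_dt = character(0)),
    indi = data.frame(primaryid = character(0), indi_drug_seq = character(0),
                      indi_pt = character(0))
  )
}

add_case <- function(tables, primaryid, caseid = primaryid,
                     fda_dt = "20200601", drugname = "REMDESIVIR",
                     role = "PS", pts = "Acute kidney injury",
                     indi = "COVID-19", outc = character(0),
                     start_dt = "20200401", event_dt = "20200410",
                     age = "60", age_cod = "YR", sex = "M",
                     occp = "MD", country = "US") {
  tables$demo[nrow(tables$demo) + 1L, ] <-
    c(primaryid, caseid, fda_dt, event_dt, age, age_cod, sex, occp, country)
  for (k in seq_along(drugname)) {
    tables$drug[nrow(tables$drug) + 1L, ] <-
      c(primaryid, as.character(k), role[min(k, length(role))],
        drugname[k], drugname[k])
  }
  for (pt in pts) {
    tables$reac[nrow(tables$reac) + 1L, ] <- c(primaryid, pt)
  }
  for (oc in outc) {
    tables$outc[nrow(tables$outc) + 1L, ] <- c(primaryid, oc)
  }
  for (ind in indi) {
    tables$indi[nrow(tables$indi) + 1L, ] <- c(primaryid, "1", ind)
  }
  tables$ther[nrow(tables$ther) + 1L, ] <- c(primaryid, "1", start_dt)
  tables
}
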