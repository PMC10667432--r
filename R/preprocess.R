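# Deleted-report removal, version deduplication, and construction of the
# primary-suspect cohort. The counting unit everywhere downstream is the
# deduplicated report (one row per CASEID), which is what the
# disproportionality tables count.

#' Remove deleted cases
#'
#' Drops every DEMO row whose CASEID is on the deleted list, together with
#' all child-table rows of the removed report versions. Deleted CASEIDs not
#' present in the data are a no-op (counted).
#'
#' @param raw A `faers_raw` object.
#' @return A `faers_raw` with deleted cases removed; `attr(, "counters")`
#'   gains `deleted_removed` (demo rows removed) and `deleted_unmatched`.
#' @export
drop_deleted <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  counters <- attr(raw, "counters")
  del <- raw$deleted
  hit <- raw$demo$caseid %in% del
  counters$deleted_removed <- sum(hit)
  counters$deleted_unmatched <- sum(!del %in% raw$demo$caseid)
  raw$demo <- raw$demo[!hit]
  raw <- .drop_child_rows(raw)
  attr(raw, "counters") <- counters
  raw
}

# keep only child rows whose primaryid survives in demo
.drop_child_rows <- function(raw) {
  ids <- unique(raw$demo$primaryid)
  for (tb in c("drug", "reac", "ther", "outc", "indi")) {
    raw[[tb]] <- raw[[tb]][primaryid %in% ids]
  }
  raw
}

#' Deduplicate report versions
#'
#' FAERS cases accumulate versions as follow-up reports arrive; each version
#' has its own PRIMARYID while sharing the CASEID. Per the FDA rule, the
#' surviving version per CASEID is the one with the latest FDA_DT, ties
#' broken by the numerically highest PRIMARYID. Child-table rows of
#' discarded versions are dropped with them. Rows with a blank CASEID are
#' kept as their own singletons (counted). Idempotent.
#'
#' @param raw A `faers_raw` object.
#' @return Deduplicated `faers_raw`; `attr(, "counters")` gains
#'   `duplicates_removed` and `blank_caseid`.
#' @export
deduplicate_reports <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  counters <- attr(raw, "counters")
  demo <- raw$demo
  blank <- is.na(demo$caseid) | !nzchar(demo$caseid)
  counters$blank_caseid <- sum(blank)
  keyed <- demo[!blank]
  if (nrow(keyed) > 0L) {
    ord <- order(keyed$caseid,
                 faers_date_key(keyed$fda_dt),
                 .primaryid_key(keyed$primaryid))
    keyed <- keyed[ord]
    last <- !duplicated(keyed$caseid, fromLast = TRUE)
    keyed <- keyed[last]
  }
  counters$duplicates_removed <- nrow(demo) - (nrow(keyed) + sum(blank))
  raw$demo <- data.table::rbindlist(list(keyed, demo[blank]))
  raw <- .drop_child_rows(raw)
  attr(raw, "counters") <- counters
  raw
}

# numeric when possible (the FAERS convention), stable fallback otherwise
.primaryid_key <- function(id) {
  key <- suppressWarnings(as.numeric(id))
  if (anyNA(key)) key[is.na(key)] <- as.numeric(factor(id[is.na(key)])) - 1e9
  key
}

#' Convert FAERS AGE/AGE_COD pairs to years
#'
#' Units handled: `YR` (as-is), `MON` (/12), `WK` (/52.14), `DY` (/365.25).
#' Any other or missing unit code yields `NA`.
#'
#' @param age Character or numeric vector of ages.
#' @param age_cod Character vector of unit codes.
#' @return Numeric vector of ages in years.
#' @export
age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  u <- toupper(trimws(age_cod))
  div <- c(YR = 1, MON = 12, WK = 52.14, DY = 365.25)
  out <- a / unname(div[u])
  out[!u %in% names(div)] <- NA_real_
  out
}

#' Classify report seriousness from outcome codes
#'
#' A report is serious iff it carries at least one outcome code; the FAERS
#' codes DE (death), LT (life-threatening), HO (hospitalization), DS
#' (disability), CA (congenital anomaly), RI (required intervention) and OT
#' (other serious medical event) all qualify. Unknown codes are tallied under
#' `"unknown"` and still make the report serious.
#'
#' @param codes Character vector of outcome codes for one report.
#' @return List with `serious` (logical) and `tally` (named integer over
#'   DE/LT/HO/DS/CA/RI/OT/unknown).
#' @export
classify_seriousness <- function(codes) {
  known <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  codes <- toupper(trimws(codes))
  codes <- codes[nzchar(codes) & !is.na(codes)]
  lab <- ifelse(codes %in% known, codes, "unknown")
  tally <- table(factor(lab, levels = c(known, "unknown")))
  list(serious = length(codes) > 0L,
       tally = setNames(as.integer(tally), names(tally)))
}

#' Build the analysis cohort with primary-suspect target flags
#'
#' Collapses the (already deduplicated) tables into one row per report and
#' flags target exposure: a report is target-exposed iff at least one of its
#' DRUG rows matches a name pattern (case-insensitive substring on DRUGNAME
#' or PROD_AI) *and* that row's role is PS (primary suspect). Matching rows
#' with other roles (SS/C/I) do not qualify. `target_start_dt` is the
#' earliest full-precision START_DT among matching PS drug rows (THER joined
#' via DSG_DRUG_SEQ = DRUG_SEQ); partial start dates are recorded via
#' `start_partial_only` so the onset stage can report them as such.
#'
#' @param raw A deduplicated `faers_raw`.
#' @param patterns Character vector of drug-name patterns, e.g.
#'   `c("sacituzumab govitecan", "trodelvy")`.
#' @return A `faers_cohort` data.table, one row per report: identifiers,
#'   demographics, `serious`, list-columns `outc_codes`, `events`
#'   (normalized PTs), `indications`, and the target exposure fields.
#' @export
build_cohort <- function(raw, patterns) {
  stopifnot(inherits(raw, "faers_raw"), length(patterns) > 0L)
  drug <- raw$drug
  hay_name <- toupper(drug$drugname)
  hay_ai <- toupper(drug$prod_ai)
  hit <- rep(FALSE, nrow(drug))
  for (p in toupper(patterns)) {
    hit <- hit | grepl(p, hay_name, fixed = TRUE) | grepl(p, hay_ai, fixed = TRUE)
  }
  is_ps <- toupper(drug$role_cod) == "PS"
  match_ps <- hit & is_ps
  target_ids <- unique(drug$primaryid[match_ps])

  # earliest full-precision start date among matching PS rows
  md <- drug[match_ps, .(primaryid, drug_seq)]
  ther <- raw$ther[md, on = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq"),
                   nomatch = NULL]
  ther[, days := faers_date_days(start_dt)]
  starts <- ther[, .(
    target_start_dt = if (all(is.na(days))) NA_character_ else
      start_dt[which.min(days)],
    start_partial_only = all(is.na(days)) &&
      any(!is.na(start_dt) & nchar(start_dt) < 8L)
  ), by = primaryid]

  ev <- raw$reac[, .(events = list(unique(normalize_pt(pt)))), by = primaryid]
  oc <- raw$outc[, .(outc_codes = list(toupper(trimws(outc_cod)))), by = primaryid]
  ind <- raw$indi[md, on = c(primaryid = "primaryid", indi_drug_seq = "drug_seq"),
                  nomatch = NULL][
    , .(indications = list(unique(normalize_pt(indi_pt)))), by = primaryid]

  cohort <- data.table::copy(raw$demo)
  cohort[, age_years := age_in_years(age, age_cod)]
  cohort[, year := faers_date_year(fda_dt)]
  cohort[, c("age", "age_cod") := NULL]
  cohort <- ev[cohort, on = "primaryid"]
  cohort <- oc[cohort, on = "primaryid"]
  cohort <- ind[cohort, on = "primaryid"]
  cohort <- starts[cohort, on = "primaryid"]
  empty_chr <- list(character(0))
  cohort[vapply(events, is.null, TRUE), events := empty_chr]
  cohort[vapply(outc_codes, is.null, TRUE), outc_codes := empty_chr]
  cohort[vapply(indications, is.null, TRUE), indications := empty_chr]
  cohort[is.na(start_partial_only), start_partial_only := FALSE]
  cohort[, serious := lengths(outc_codes) > 0L]
  cohort[, is_target_ps := primaryid %in% target_ids]
  data.table::setcolorder(cohort, c("primaryid", "caseid", "fda_dt", "event_dt"))
  class(cohort) <- c("faers_cohort", class(cohort))
  cohort[]
}

#' Long (report, event) pairs of a cohort
#'
#' @param cohort A `faers_cohort`.
#' @param target_only Restrict to target-exposed reports.
#' @return data.table with columns `primaryid`, `is_target_ps`, `event`
#'   (one row per distinct report-PT pair).
#' @export
cohort_events <- function(cohort, target_only = FALSE) {
  if (target_only) cohort <- cohort[is_target_ps == TRUE]
  data.table::data.table(
    primaryid = rep(cohort$primaryid, lengths(cohort$events)),
    is_target_ps = rep(cohort$is_target_ps, lengths(cohort$events)),
    event = unlist(cohort$events, use.names = FALSE)
  )
}

#' Cohort-level tally of serious outcome codes
#'
#' Reports may carry several codes, so the tally total can exceed the number
#' of serious reports.
#'
#' @param cohort A `faers_cohort` (typically the target subset).
#' @return Named integer vector over DE/LT/HO/DS/CA/RI/OT/unknown.
#' @export
outcome_tally <- function(cohort) {
  codes <- unlist(cohort$outc_codes, use.names = FALSE)
  classify_seriousness(if (length(codes)) codes else character(0))$tally
}
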