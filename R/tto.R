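# Time to onset: days from therapy start of the target drug (START_DT of
# the matching primary-suspect drug row) to adverse-event onset (EVENT_DT).
# Reports with missing or partial dates, or with the event dated before the
# therapy start, are excluded with an explicit reason — the reasons partition
# the target cohort, so nothing is dropped silently.

TTO_EXCLUSION_REASONS <- c("missing_start", "missing_event", "partial_date",
                           "negative_interval")

#' Resolve each target report to an onset interval or exclusion reason
#'
#' Exactly one of `onset_days` / `exclusion_reason` is set per report:
#' * `partial_date` — the event date, or the only available start dates, have
#'   year/month precision;
#' * `missing_start` / `missing_event` — the date is absent entirely;
#' * `negative_interval` — the event is dated before the therapy start;
#' * otherwise `onset_days = EVENT_DT - START_DT` in calendar days (day 0,
#'   onset on the start date, is valid).
#'
#' @param cohort A `faers_cohort`; only target-exposed rows are used.
#' @return data.table with `primaryid`, `start_dt`, `event_dt`,
#'   `onset_days`, `exclusion_reason`.
#' @export
compute_onset <- function(cohort) {
  tg <- cohort[is_target_ps == TRUE]
  start <- tg$target_start_dt
  event <- tg$event_dt
  sd_days <- faers_date_days(start)
  ev_days <- faers_date_days(event)
  ev_partial <- !is.na(event) & nchar(event) < 8L

  reason <- rep(NA_character_, nrow(tg))
  reason[is.na(sd_days) & tg$start_partial_only] <- "partial_date"
  reason[is.na(sd_days) & !tg$start_partial_only] <- "missing_start"
  open <- is.na(reason)
  reason[open & is.na(event)] <- "missing_event"
  open <- is.na(reason)
  # calendar-invalid 8-digit dates (e.g. 20220231) are treated like partials
  reason[open & (ev_partial | is.na(ev_days))] <- "partial_date"
  open <- is.na(reason)
  reason[open & ev_days < sd_days] <- "negative_interval"

  onset <- ifelse(is.na(reason), ev_days - sd_days, NA_integer_)
  data.table::data.table(
    primaryid = tg$primaryid, start_dt = start, event_dt = event,
    onset_days = as.integer(onset), exclusion_reason = reason
  )
}

#' Onset observations per (report, PT) pair
#'
#' For per-event onset tables each report contributes one observation to
#' every PT it carries (the overall summary stays per-report).
#'
#' @param cohort A `faers_cohort`.
#' @return [compute_onset()] output expanded with a `pt` column.
#' @export
compute_onset_by_pt <- function(cohort) {
  obs <- compute_onset(cohort)
  tg <- cohort[is_target_ps == TRUE]
  idx <- rep(seq_len(nrow(obs)), lengths(tg$events))
  out <- obs[idx]
  out[, pt := unlist(tg$events, use.names = FALSE)]
  data.table::setcolorder(out, c("primaryid", "pt"))
  out[]
}

#' Day-range bins used in onset summaries
#' @keywords internal
TTO_BINS <- data.table::data.table(
  label = c("0-30d", "31-90d", "91-180d", "181-360d", ">360d"),
  lo = c(0L, 31L, 91L, 181L, 361L),
  hi = c(30L, 90L, 180L, 360L, .Machine$integer.max)
)

#' Summarize onset intervals
#'
#' Median and quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) unless `quantile_type` says otherwise; day
#' bins are `0-30`, `31-90`, `91-180`, `181-360`, `>360`, both ends
#' inclusive.
#'
#' @param obs Output of [compute_onset()] or [compute_onset_by_pt()].
#' @param pt Optional PT filter (requires a `pt` column).
#' @param quantile_type Passed to [stats::quantile()] (default 7, linear
#'   interpolation).
#' @return A `tto_summary` list: `n_with_onset`, `n_excluded` (named by
#'   reason), `mean`, `median`, `q1`, `q3`, and `bins` (data.table).
#' @export
summarize_tto <- function(obs, pt = NULL, quantile_type = 7) {
  if (!is.null(pt)) {
    stopifnot("pt" %in% names(obs))
    target_pt <- normalize_pt(pt)
    obs <- obs[obs$pt == target_pt]
  }
  excl <- table(factor(obs$exclusion_reason, levels = TTO_EXCLUSION_REASONS))
  x <- obs$onset_days[!is.na(obs$onset_days)]
  bins <- data.table::copy(TTO_BINS)
  if (length(x) == 0L) {
    bins[, n := 0L]
    return(structure(list(n_with_onset = 0L,
                          n_excluded = setNames(as.integer(excl), names(excl)),
                          mean = NA_real_, median = NA_real_,
                          q1 = NA_real_, q3 = NA_real_, bins = bins),
                     class = "tto_summary"))
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = quantile_type))
  bins[, n := vapply(seq_len(nrow(bins)),
                     function(i) sum(x >= bins$lo[i] & x <= bins$hi[i]), 0L)]
  structure(list(
    n_with_onset = length(x),
    n_excluded = setNames(as.integer(excl), names(excl)),
    mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
    bins = bins
  ), class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("<tto_summary> n =", x$n_with_onset, " median =", x$median,
      " (Q1", x$q1, ", Q3", x$q3, ")\n")
  invisible(x)
}

#' Per-PT onset table (median and IQR per event)
#'
#' @param obs Output of [compute_onset_by_pt()].
#' @param min_n Only PTs with at least this many recorded onsets are listed.
#' @param quantile_type Quartile method, as in [summarize_tto()].
#' @return data.table `pt`, `n`, `median`, `q1`, `q3`, sorted by `n`
#'   descending then PT.
#' @export
tto_by_pt <- function(obs, min_n = 1, quantile_type = 7) {
  inc <- obs[!is.na(onset_days)]
  out <- inc[, {
    q <- unname(quantile(onset_days, c(0.25, 0.5, 0.75), type = quantile_type))
    .(n = .N, median = q[2], q1 = q[1], q3 = q[3])
  }, by = pt]
  out <- out[n >= min_n]
  data.table::setorderv(out, c("n", "pt"), order = c(-1L, 1L))
  out[]
}
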