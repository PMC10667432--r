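# Disproportionality statistics on report-level 2x2 contingency tables.
#
# For one event (PT or SOC) the table is
#        event   other events
# drug     a         b
# other    c         d
# where "drug" means target-exposed (primary suspect) reports and a report
# contributes at most 1 to each cell. Four algorithms are computed per table:
#   ROR  = ad/(bc), Wald CI on the log scale
#   PRR  = (a/(a+b)) / (c/(c+d)), with the uncorrected Pearson chi-squared
#   IC   = log2( a*n / ((a+b)(a+c)) ), with the BCPNN Beta-prior shrinkage
#          moments E(IC), V(IC) and IC025 = E(IC) - 2*sqrt(V(IC))
#   EBGM = a*n / ((a+b)(a+c)) (closed-form relative reporting ratio; note the
#          algebraic identity IC = log2(EBGM)), with log-normal-style bounds
# No continuity/Haldane correction is applied anywhere: zero cells make the
# affected estimate undefined (NA), and an undefined estimate simply fails
# its signal criterion.

#' Build a 2x2 contingency table for one event
#'
#' Report-level counting: at SOC level a report with several PTs inside one
#' SOC still contributes a single count.
#'
#' @param cohort A `faers_cohort` (all reports, with target flags).
#' @param event Event label: a normalized PT, or a SOC name when
#'   `level = "soc"`.
#' @param level `"pt"` or `"soc"`.
#' @param meddra A `meddra_map`; required when `level = "soc"`.
#' @return A `contingency` list with integer fields `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(cohort, event, level = c("pt", "soc"),
                              meddra = NULL) {
  level <- match.arg(level)
  ev <- cohort_events(cohort)
  if (level == "soc") {
    stopifnot(!is.null(meddra))
    ev[, event := map_pt_to_soc(meddra, event)]
  } else {
    ev[, event := normalize_pt(event)]
  }
  ev <- unique(ev[, .(primaryid, is_target_ps, event)])
  lbl <- if (level == "pt") normalize_pt(event) else event
  has <- ev[event == lbl, .(primaryid, is_target_ps)]
  has <- unique(has)
  n_target <- sum(cohort$is_target_ps)
  n_other <- nrow(cohort) - n_target
  a <- sum(has$is_target_ps)
  c_ <- nrow(has) - a
  contingency(a, n_target - a, c_, n_other - c_)
}

#' Construct a contingency table from counts
#'
#' @param a Reports with target drug and target event.
#' @param b Reports with target drug, other events.
#' @param c Reports with other drugs, target event.
#' @param d Reports with other drugs, other events.
#' @return A `contingency` list with `n = a+b+c+d`.
#' @export
contingency <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "contingency")
}

#' BCPNN prior constants
#'
#' The standard published choice: marginal Beta priors with
#' `alpha1 = beta1 = 1`, joint prior strength `alpha = beta = 2`, and
#' `gamma11 = 1`; the joint prior parameter gamma is recomputed from each
#' table so that the prior IC is centred at zero.
#'
#' @param alpha,beta,alpha1,beta1,gamma11 Positive reals.
#' @return A `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                         gamma11 = 1) {
  stopifnot(alpha > 0, beta > 0, alpha1 > 0, beta1 > 0, gamma11 > 0)
  structure(list(alpha = alpha, beta = beta, alpha1 = alpha1, beta1 = beta1,
                 gamma11 = gamma11), class = "bcpnn_priors")
}

# vectorized engine shared by the scalar wrappers and screen_signals();
# a,b,c,d numeric vectors of equal length
.signal_stats <- function(a, b, cc, d, priors = bcpnn_priors()) {
  a <- as.numeric(a); b <- as.numeric(b)
  cc <- as.numeric(cc); d <- as.numeric(d)
  n <- a + b + cc + d
  pos <- a > 0 & b > 0 & cc > 0 & d > 0
  se <- ifelse(pos, sqrt(1 / a + 1 / b + 1 / cc + 1 / d), NA_real_)

  ror <- ifelse(b > 0 & cc > 0 & a > 0 & d > 0, (a * d) / (b * cc), NA_real_)
  ror_low <- exp(log(ror) - 1.96 * se)
  ror_high <- exp(log(ror) + 1.96 * se)

  prr <- ifelse(a + b > 0 & cc > 0 & cc + d > 0,
                (a / (a + b)) / (cc / (cc + d)), NA_real_)
  chi_den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- ifelse(chi_den > 0, n * (a * d - b * cc)^2 / chi_den, NA_real_)

  margins_ok <- (a + b) > 0 & (a + cc) > 0
  ebgm <- ifelse(margins_ok, a * n / ((a + b) * (a + cc)), NA_real_)
  ebgm05 <- exp(log(ebgm) - 1.96 * se)
  ebgm95 <- exp(log(ebgm) + 1.96 * se)
  ic <- ifelse(margins_ok & a > 0, log2(a * n / ((a + b) * (a + cc))), NA_real_)

  p <- priors
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((a + b + p$alpha1) * (a + cc + p$beta1))
  ic_e <- log2((a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
                 ((n + gamma) * (a + b + p$alpha1) * (a + cc + p$beta1)))
  ic_v <- (1 / log(2)^2) * (
    (n - a + gamma - p$gamma11) / ((a + p$gamma11) * (1 + n + gamma)) +
    (n - (a + b) + p$alpha - p$alpha1) / ((a + b + p$alpha1) * (1 + n + p$alpha)) +
    (n - (a + cc) + p$beta - p$beta1) / ((a + cc + p$beta1) * (1 + n + p$beta))
  )
  ic025 <- ic_e - 2 * sqrt(ic_v)

  data.table::data.table(
    a = a, b = b, c = cc, d = d, n = n,
    ror = ror, ror_low = ror_low, ror_high = ror_high,
    prr = prr, chi2 = chi2,
    ic = ic, ic_e = ic_e, ic_v = ic_v, ic025 = ic025,
    ebgm = ebgm, ebgm05 = ebgm05, ebgm95 = ebgm95
  )
}

.as_cells <- function(t) {
  stopifnot(inherits(t, "contingency"))
  list(a = t$a, b = t$b, cc = t$c, d = t$d)
}

#' Reporting odds ratio with 95% Wald CI
#'
#' `ROR = ad/(bc)`; `CI = exp(log ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d))`.
#' Any zero cell makes estimate and CI undefined (`NA`) — no continuity
#' correction is applied.
#'
#' @param t A `contingency` table.
#' @return List with `ror`, `ci_low`, `ci_high`.
#' @export
ror <- function(t) {
  x <- .as_cells(t)
  s <- .signal_stats(x$a, x$b, x$cc, x$d)
  list(ror = s$ror, ci_low = s$ror_low, ci_high = s$ror_high)
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`;
#' `chi2 = n*(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, uncorrected.
#'
#' @param t A `contingency` table.
#' @return List with `prr`, `chi2`.
#' @export
prr <- function(t) {
  x <- .as_cells(t)
  s <- .signal_stats(x$a, x$b, x$cc, x$d)
  list(prr = s$prr, chi2 = s$chi2)
}

#' BCPNN information component with shrinkage moments
#'
#' Point `IC = log2(a*n/((a+b)(a+c)))`; `E(IC)` and `V(IC)` are the
#' closed-form posterior moments under the Beta priors in `p` (with the
#' joint prior parameter gamma recomputed from the table), and
#' `IC025 = E(IC) - 2*sqrt(V(IC))`. With `a = 0` the shrunken moments are
#' still defined while the point IC is not.
#'
#' @param t A `contingency` table.
#' @param p A [bcpnn_priors()].
#' @return List with `ic`, `ic_e`, `ic_v`, `ic025`.
#' @export
bcpnn_ic <- function(t, p = bcpnn_priors()) {
  x <- .as_cells(t)
  s <- .signal_stats(x$a, x$b, x$cc, x$d, priors = p)
  list(ic = s$ic, ic_e = s$ic_e, ic_v = s$ic_v, ic025 = s$ic025)
}

#' Empirical Bayes geometric mean (closed form) with 95% bounds
#'
#' `EBGM = a*n/((a+b)(a+c))` — the relative reporting ratio; bounds
#' `exp(log EBGM -/+ 1.96*sqrt(1/a+1/b+1/c+1/d))`, the lower one being
#' EBGM05. This is the closed form used for MGPS-style screening here; it is
#' not the DuMouchel gamma-mixture EM shrinker.
#'
#' @param t A `contingency` table.
#' @return List with `ebgm`, `ebgm05`, `ebgm95`.
#' @export
ebgm <- function(t) {
  x <- .as_cells(t)
  s <- .signal_stats(x$a, x$b, x$cc, x$d)
  list(ebgm = s$ebgm, ebgm05 = s$ebgm05, ebgm95 = s$ebgm95)
}

#' Signal criteria and four-way consensus
#'
#' Flags, per the standard thresholds: `ror_pos` iff the ROR CI lower bound
#' exceeds 1; `prr_pos` iff `PRR >= 2` and `chi2 >= 4`; `bcpnn_pos` iff
#' `IC025 > 0`; `mgps_pos` iff `EBGM05 > 2`; `min_count_ok` iff `a >= 3`.
#' `consensus` is the conjunction of all five. An undefined (`NA`) estimate
#' fails its criterion.
#'
#' @param m A one-row data.frame/data.table with columns `a`, `ror_low`,
#'   `prr`, `chi2`, `ic025`, `ebgm05` (as produced by the algorithm
#'   functions), or a list with those elements. Vectorized over rows.
#' @param min_a Minimum report count (default 3).
#' @param thresholds Named list overriding `prr`, `chi2`, `ebgm05` cutoffs.
#' @return data.table of logical flags plus `consensus`.
#' @export
evaluate_criteria <- function(m, min_a = 3,
                              thresholds = list(prr = 2, chi2 = 4, ebgm05 = 2)) {
  m <- data.table::as.data.table(m)
  tt <- function(x, cut, strict = FALSE) {
    r <- if (strict) x > cut else x >= cut
    r & !is.na(x)
  }
  out <- data.table::data.table(
    ror_pos = tt(m$ror_low, 1, strict = TRUE),
    prr_pos = tt(m$prr, thresholds$prr) & tt(m$chi2, thresholds$chi2),
    bcpnn_pos = tt(m$ic025, 0, strict = TRUE),
    mgps_pos = tt(m$ebgm05, thresholds$ebgm05, strict = TRUE),
    min_count_ok = tt(m$a, min_a)
  )
  out[, consensus := ror_pos & prr_pos & bcpnn_pos & mgps_pos & min_count_ok]
  out[]
}

#' Screen every event for disproportionality signals
#'
#' Builds all report-level 2x2 tables at the requested MedDRA level in one
#' pass, computes the four algorithms and the consensus flags, and marks
#' events belonging to excluded SOCs. Excluded events stay in the raw output
#' with `excluded = TRUE`; the consensus report ([consensus_report()]) drops
#' them. Output is sorted by `a` descending, ties broken by event name.
#'
#' @param cohort A `faers_cohort` (all reports, with target flags).
#' @param level `"pt"` or `"soc"`.
#' @param meddra A `meddra_map`; required for SOC level and for SOC
#'   exclusions at PT level.
#' @param soc_exclusions Character vector of SOC names to exclude.
#' @param min_a Minimum report count for the consensus criterion.
#' @param priors BCPNN priors.
#' @return data.table, one row per event with `a >= 1`: counts, all
#'   estimates and bounds, criterion flags, `consensus`, `soc`, `excluded`.
#' @export
screen_signals <- function(cohort, level = c("pt", "soc"), meddra = NULL,
                           soc_exclusions = character(0), min_a = 3,
                           priors = bcpnn_priors()) {
  level <- match.arg(level)
  ev <- cohort_events(cohort)
  if (level == "soc") {
    stopifnot(!is.null(meddra))
    ev[, event := map_pt_to_soc(meddra, event)]
  }
  ev <- unique(ev[, .(primaryid, is_target_ps, event)])
  n_target <- sum(cohort$is_target_ps)
  n_total <- nrow(cohort)
  counts <- ev[, .(a = sum(is_target_ps), tot = .N), by = event]
  counts[, c_cell := tot - a]
  res <- .signal_stats(counts$a, n_target - counts$a,
                       counts$c_cell, (n_total - n_target) - counts$c_cell,
                       priors = priors)
  res[, event := counts$event]
  res <- cbind(res, evaluate_criteria(res, min_a = min_a))
  if (level == "pt") {
    res[, soc := if (is.null(meddra)) NA_character_ else
      map_pt_to_soc(meddra, event)]
    res[, excluded := !is.na(soc) & soc %in% soc_exclusions]
  } else {
    res[, soc := event]
    res[, excluded := event %in% soc_exclusions]
  }
  res <- res[a >= 1]
  data.table::setorderv(res, c("a", "event"), order = c(-1L, 1L))
  data.table::setcolorder(res, c("event", "soc"))
  attr(res, "level") <- level
  res[]
}

#' Consensus report: significant, non-excluded signals
#'
#' @param screened Output of [screen_signals()].
#' @return Rows reaching four-way consensus whose SOC is not excluded.
#' @export
consensus_report <- function(screened) {
  screened[consensus == TRUE & excluded == FALSE]
}
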