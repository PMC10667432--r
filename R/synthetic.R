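# Seeded generator of FAERS-like quarters with known ground truth. The
# generative model mirrors the relational structure of the real database:
# versioned reports keyed by PRIMARYID/CASEID, PS/SS/C/I drug roles,
# PT-coded events, therapy start dates with realistic missingness, outcome
# codes, and a deleted-case list. Signal structure is planted by
# re-weighting chosen PTs in target-exposed reports by a relative reporting
# rate R, so every screening statistic can be checked against a closed-form
# expectation.

#' Configuration of the synthetic report generator
#'
#' Defaults describe the reference simulation used throughout the package's
#' validation: 50,000 reports, 2% target-drug prevalence, 200 background PTs
#' with Dirichlet(0.5) frequencies, three planted PTs at relative rate 10,
#' 1+Poisson(1.5) events per report, 5% duplicated report versions (10% of
#' them FDA_DT ties), 1% deleted cases, start/event dates missing for ~35%
#' of reports each plus 5% partial-precision dates, and a log-normal onset
#' delay with median 14 days.
#'
#' @param n_reports Number of distinct cases.
#' @param n_background_drugs Background drug universe size.
#' @param n_background_pts PT universe size.
#' @param dirichlet_conc Concentration of the symmetric Dirichlet from which
#'   background PT frequencies are drawn (small values give realistic
#'   rare-event tails and exercise zero-cell code paths).
#' @param target_prevalence Probability a report is target-drug exposed
#'   (role PS).
#' @param planted data.frame with columns `pt`, `rr`: PTs whose reporting
#'   rate in target reports is multiplied by `rr` (before renormalization).
#' @param events_lambda Events per report are `1 + Poisson(lambda)`.
#' @param dup_fraction Fraction of cases re-emitted as a later report
#'   version (new PRIMARYID, later FDA_DT).
#' @param dup_tie_fraction Fraction of duplicates keeping the same FDA_DT,
#'   exercising the PRIMARYID tie-break.
#' @param deleted_fraction Fraction of cases put on the deleted list.
#' @param missing_start_frac,partial_start_frac,missing_event_frac,partial_event_frac
#'   Date-quality fractions.
#' @param female_share,sex_unknown_frac Demographic mixture for sex.
#' @param age_mean,age_sd,age_missing_frac Age distribution (years).
#' @param serious_prob Probability a report carries at least one outcome code.
#' @param delay_meanlog,delay_sdlog Log-normal start-to-event delay (days).
#' @param n_soc Number of SOCs the PT universe is spread over.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports = 50000,
                             n_background_drugs = 50,
                             n_background_pts = 200,
                             dirichlet_conc = 0.5,
                             target_prevalence = 0.02,
                             planted = data.frame(
                               pt = sprintf("PT_%03d", 1:3), rr = 10),
                             events_lambda = 1.5,
                             dup_fraction = 0.05,
                             dup_tie_fraction = 0.1,
                             deleted_fraction = 0.01,
                             missing_start_frac = 0.35,
                             partial_start_frac = 0.05,
                             missing_event_frac = 0.35,
                             partial_event_frac = 0.05,
                             female_share = 0.85,
                             sex_unknown_frac = 0.06,
                             age_mean = 56, age_sd = 12,
                             age_missing_frac = 0.5,
                             serious_prob = 0.9,
                             delay_meanlog = log(14), delay_sdlog = 1.1,
                             n_soc = 20,
                             seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$target_prevalence, cfg$dup_fraction, cfg$dup_tie_fraction,
             cfg$deleted_fraction, cfg$missing_start_frac,
             cfg$partial_start_frac, cfg$missing_event_frac,
             cfg$partial_event_frac, cfg$female_share, cfg$sex_unknown_frac,
             cfg$age_missing_frac, cfg$serious_prob)
  stopifnot(all(fracs >= 0 & fracs <= 1), cfg$n_reports > 0,
            all(cfg$planted$rr >= 0))
  pts <- synthetic_pts(cfg)
  missing_planted <- setdiff(normalize_pt(cfg$planted$pt), pts)
  if (length(missing_planted) > 0L) {
    stop("planted PT(s) outside the PT universe: ",
         paste(missing_planted, collapse = ", "))
  }
  structure(cfg, class = "synthetic_config")
}

#' PT universe of a configuration
#' @param config A `synthetic_config` (or plain list with
#'   `n_background_pts`).
#' @return Character vector of PT names.
#' @export
synthetic_pts <- function(config) {
  normalize_pt(sprintf("PT_%03d", seq_len(config$n_background_pts)))
}

#' PT-to-SOC map of the synthetic universe
#' @param config A `synthetic_config`.
#' @return data.table with `pt`, `soc` (PTs assigned round-robin to SOCs).
#' @export
synthetic_pt_soc <- function(config) {
  pts <- synthetic_pts(config)
  data.table::data.table(
    pt = pts,
    soc = sprintf("SOC_%02d", (seq_along(pts) - 1L) %% config$n_soc + 1L)
  )
}

#' Background and target PT reporting probabilities
#'
#' Background frequencies are one symmetric-Dirichlet draw derived
#' deterministically from the configuration seed; target-report frequencies
#' re-weight planted PTs by their relative rate and renormalize. Both
#' [simulate_raw()] and [expected_table()] derive the same probabilities, so
#' closed-form expectations refer to the realized frequencies, not just
#' their prior mean.
#'
#' @param config A `synthetic_config`.
#' @return List with named numeric vectors `background` and `target`.
#' @export
synthetic_probs <- function(config) {
  set.seed(config$seed)
  g <- rgamma(config$n_background_pts, shape = config$dirichlet_conc, rate = 1)
  g <- pmax(g, 1e-12)
  p_bg <- g / sum(g)
  names(p_bg) <- synthetic_pts(config)
  idx <- match(normalize_pt(config$planted$pt), names(p_bg))
  if (length(idx) > 0L) {
    # planted events emulate AEs with a *typical* background reporting rate:
    # pin them at the mean frequency so the planted relative rate, not a
    # freak Dirichlet tail, decides detectability
    k <- length(idx)
    m <- 1 / config$n_background_pts
    p_bg[idx] <- m
    rest <- setdiff(seq_along(p_bg), idx)
    p_bg[rest] <- p_bg[rest] * (1 - k * m) / sum(p_bg[rest])
  }
  w <- rep(1, length(p_bg))
  w[idx] <- config$planted$rr
  p_t <- p_bg * w
  p_t <- p_t / sum(p_t)
  list(background = p_bg, target = p_t)
}

.target_drugname <- "TRODELVY"
.target_prod_ai <- "SACITUZUMAB GOVITECAN-HZIY"

# apply missing/partial corruption to a vector of YYYYMMDD strings
.corrupt_dates <- function(x, missing_frac, partial_frac) {
  u <- runif(length(x))
  part <- u >= missing_frac & u < missing_frac + partial_frac
  # half of partials keep month precision (YYYYMM), half only the year
  month_prec <- part & runif(length(x)) < 0.5
  x[month_prec] <- substr(x[month_prec], 1L, 6L)
  x[part & !month_prec] <- substr(x[part & !month_prec], 1L, 4L)
  x[u < missing_frac] <- ""
  x
}

#' Generate one synthetic quarter in memory
#'
#' @param config A `synthetic_config`.
#' @return A `faers_raw` object (same shape as [read_faers_quarter()]
#'   output) with `attr(, "ground_truth")`: the planted table, realized PT
#'   probabilities, and per-report target flags.
#' @export
simulate_raw <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  probs <- synthetic_probs(config)      # consumes seed, then reseed below
  set.seed(config$seed + 1L)
  n <- config$n_reports
  pts <- names(probs$background)

  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")
  is_target <- runif(n) < config$target_prevalence

  # calendar scaffolding (days since epoch)
  win_lo <- as.integer(as.Date("2020-04-01"))
  win_hi <- as.integer(as.Date("2023-01-31"))
  start_days <- win_lo + floor(runif(n) * (win_hi - win_lo + 1L))
  delay <- round(rlnorm(n, config$delay_meanlog, config$delay_sdlog))
  event_days <- start_days + delay
  fda_days <- event_days + 1L + floor(runif(n) * 90)

  start_dt <- .corrupt_dates(days_to_faers_date(start_days),
                             config$missing_start_frac,
                             config$partial_start_frac)
  event_dt <- .corrupt_dates(days_to_faers_date(event_days),
                             config$missing_event_frac,
                             config$partial_event_frac)
  fda_dt <- days_to_faers_date(fda_days)

  # demographics
  sex <- ifelse(runif(n) < config$sex_unknown_frac, "",
                ifelse(runif(n) < config$female_share, "F", "M"))
  age <- round(pmax(18, pmin(95, rnorm(n, config$age_mean, config$age_sd))))
  age_chr <- as.character(age)
  age_cod <- rep("YR", n)
  mon <- runif(n) < 0.02        # a few ages coded in months
  age_chr[mon] <- as.character(age[mon] * 12L)
  age_cod[mon] <- "MON"
  age_na <- runif(n) < config$age_missing_frac
  age_chr[age_na] <- ""
  age_cod[age_na] <- ""
  occ <- sample(c("MD", "PH", "CN", ""), n, replace = TRUE,
                prob = c(0.52, 0.36, 0.115, 0.005))
  country <- sample(c("US", "FR", "CA", "DE", "IT", "JP", "GB"), n,
                    replace = TRUE,
                    prob = c(0.36, 0.19, 0.12, 0.08, 0.08, 0.09, 0.08))

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age = age_chr, age_cod = age_cod, sex = sex,
    occp_cod = occ, reporter_country = country, occr_country = country
  )

  # drugs: one PS row per report; ~30% get a concomitant background drug;
  # a sliver of non-target reports carry the target drug with role C only
  bg_names <- sprintf("DRUG_%03d", seq_len(config$n_background_drugs))
  ps_drug <- ifelse(is_target, .target_drugname,
                    sample(bg_names, n, replace = TRUE))
  ps_ai <- ifelse(is_target, .target_prod_ai, ps_drug)
  drug <- data.table::data.table(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = ps_drug, prod_ai = ps_ai
  )
  con_idx <- which(runif(n) < 0.30)
  if (length(con_idx)) {
    con <- data.table::data.table(
      primaryid = primaryid[con_idx], drug_seq = "2", role_cod = "C",
      drugname = sample(bg_names, length(con_idx), replace = TRUE),
      prod_ai = ""
    )
    con[, prod_ai := drugname]
    drug <- data.table::rbindlist(list(drug, con))
  }
  tcon_idx <- which(!is_target & runif(n) < 0.005)
  if (length(tcon_idx)) {
    drug <- data.table::rbindlist(list(drug, data.table::data.table(
      primaryid = primaryid[tcon_idx], drug_seq = "3", role_cod = "C",
      drugname = .target_drugname, prod_ai = .target_prod_ai
    )))
  }

  # events: 1 + Poisson(lambda) PTs per report, planted PTs re-weighted in
  # target reports
  k <- 1L + rpois(n, config$events_lambda)
  rep_id <- rep(primaryid, k)
  rep_target <- rep(is_target, k)
  ev <- character(length(rep_id))
  n_t <- sum(rep_target)
  if (n_t > 0L) ev[rep_target] <- sample(pts, n_t, replace = TRUE,
                                         prob = probs$target)
  if (n_t < length(ev)) ev[!rep_target] <- sample(pts, length(ev) - n_t,
                                                  replace = TRUE,
                                                  prob = probs$background)
  reac <- data.table::data.table(primaryid = rep_id, pt = ev)

  ther <- data.table::data.table(primaryid = primaryid, dsg_drug_seq = "1",
                                 start_dt = start_dt)

  serious <- runif(n) < config$serious_prob
  n_codes <- 1L + rpois(sum(serious), 0.35)
  oc_id <- rep(primaryid[serious], n_codes)
  oc <- sample(c("OT", "HO", "DE", "LT", "DS", "RI", "CA"),
               length(oc_id), replace = TRUE,
               prob = c(0.50, 0.21, 0.19, 0.06, 0.025, 0.01, 0.005))
  outc <- unique(data.table::data.table(primaryid = oc_id, outc_cod = oc))

  ind_pool <- c("Triple negative breast cancer",
                "Product used for unknown indication",
                "Breast cancer metastatic", "Breast cancer",
                "Transitional cell carcinoma", "Urothelial carcinoma")
  indi_pt <- ifelse(is_target,
                    sample(ind_pool, n, replace = TRUE,
                           prob = c(0.51, 0.19, 0.07, 0.06, 0.04, 0.03)),
                    "Product used for unknown indication")
  indi <- data.table::data.table(primaryid = primaryid, indi_drug_seq = "1",
                                 indi_pt = indi_pt)

  # duplicate report versions: same CASEID, new (higher) PRIMARYID, later
  # FDA_DT except for deliberate ties
  n_dup <- as.integer(round(config$dup_fraction * n))
  if (n_dup > 0L) {
    dup_i <- sample.int(n, n_dup)
    tie <- runif(n_dup) < config$dup_tie_fraction
    d2 <- demo[dup_i]
    old_pid <- d2$primaryid
    d2[, primaryid := paste0(caseid, "2")]
    bump <- ifelse(tie, 0L, 1L + floor(runif(n_dup) * 60))
    d2[, fda_dt := days_to_faers_date(fda_days[dup_i] + bump)]
    demo <- data.table::rbindlist(list(demo, d2))
    clone <- function(dt) {
      sub <- dt[primaryid %in% old_pid]
      sub[, primaryid := paste0(substr(primaryid, 1L, 8L), "2")]
      sub
    }
    drug <- data.table::rbindlist(list(drug, clone(drug)))
    reac <- data.table::rbindlist(list(reac, clone(reac)))
    ther <- data.table::rbindlist(list(ther, clone(ther)))
    outc <- data.table::rbindlist(list(outc, clone(outc)))
    indi <- data.table::rbindlist(list(indi, clone(indi)))
  }

  n_del <- as.integer(round(config$deleted_fraction * n))
  deleted <- if (n_del > 0L) sample(caseid, n_del) else character(0)

  raw <- structure(
    list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc,
         indi = indi, deleted = deleted),
    class = "faers_raw",
    counters = list()
  )
  attr(raw, "ground_truth") <- list(
    planted = data.table::data.table(pt = normalize_pt(config$planted$pt),
                                     rr = config$planted$rr),
    probs = probs,
    target_caseids = caseid[is_target],
    n_duplicates = n_dup, n_deleted = n_del
  )
  raw
}

#' Generate a synthetic quarter on disk
#'
#' Writes the six quarter tables plus the deleted list in the ingest
#' dialect, a PT-to-SOC map, and a ground-truth TSV of planted signals with
#' their expected `a` cell.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory.
#' @param dialect A [faers_dialect()].
#' @return Invisibly, a list with `dir`, `meddra_path`, `truth_path`, and
#'   the in-memory `raw` object.
#' @export
simulate_quarter <- function(config, out_dir, dialect = faers_dialect()) {
  raw <- simulate_raw(config)
  write_faers_quarter(raw, out_dir, dialect)
  map <- synthetic_pt_soc(config)
  meddra_path <- file.path(out_dir, "pt_soc_map.csv")
  data.table::fwrite(map, meddra_path)
  truth <- data.table::copy(attr(raw, "ground_truth")$planted)
  truth[, expected_a := vapply(pt, function(p)
    expected_table(config, p)$a, numeric(1))]
  truth_path <- file.path(out_dir, "ground_truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t")
  invisible(list(dir = out_dir, meddra_path = meddra_path,
                 truth_path = truth_path, raw = raw))
}

#' Closed-form expected contingency table under the generative model
#'
#' A report with event probability `p` per draw and `1 + Poisson(lambda)`
#' draws carries the event with probability `1 - (1-p) * exp(-lambda*p)`
#' (report-level counting saturates repeats). Expectations refer to the
#' post-pipeline data: the deleted fraction is removed and duplicate
#' versions collapse back onto their cases.
#'
#' @param config A `synthetic_config`.
#' @param pt One PT name from the universe.
#' @return A `contingency` of expected (non-integer) counts.
#' @export
expected_table <- function(config, pt) {
  probs <- synthetic_probs(config)
  pt <- normalize_pt(pt)
  stopifnot(pt %in% names(probs$background))
  p_has <- function(p) 1 - (1 - p) * exp(-config$events_lambda * p)
  keep <- config$n_reports * (1 - config$deleted_fraction)
  n_t <- keep * config$target_prevalence
  n_o <- keep - n_t
  pa <- p_has(probs$target[[pt]])
  pc <- p_has(probs$background[[pt]])
  contingency(n_t * pa, n_t * (1 - pa), n_o * pc, n_o * (1 - pc))
}
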