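# In-code fixtures and independent oracles shared across the suite.

TARGET_PATTERNS <- c("sacituzumab govitecan", "trodelvy")

# assemble a faers_raw from partial tables, filling schema defaults
as_faers_raw <- function(demo = NULL, drug = NULL, reac = NULL, ther = NULL,
                         outc = NULL, indi = NULL, deleted = character(0)) {
  defaults <- list(
    demo = data.table::data.table(primaryid = character(), caseid = character(),
      fda_dt = character(), event_dt = character(), age = character(),
      age_cod = character(), sex = character(), occp_cod = character(),
      reporter_country = character(), occr_country = character()),
    drug = data.table::data.table(primaryid = character(), drug_seq = character(),
      role_cod = character(), drugname = character(), prod_ai = character()),
    reac = data.table::data.table(primaryid = character(), pt = character()),
    ther = data.table::data.table(primaryid = character(),
      dsg_drug_seq = character(), start_dt = character()),
    outc = data.table::data.table(primaryid = character(), outc_cod = character()),
    indi = data.table::data.table(primaryid = character(),
      indi_drug_seq = character(), indi_pt = character())
  )
  fill <- function(x, template) {
    if (is.null(x)) return(template)
    x <- data.table::as.data.table(x)
    for (col in names(template)) {
      if (!col %in% names(x)) x[, (col) := ""]
    }
    out <- x[, names(template), with = FALSE]
    for (j in names(out)) data.table::set(out, j = j, value = as.character(out[[j]]))
    out
  }
  raw <- list(demo = fill(demo, defaults$demo), drug = fill(drug, defaults$drug),
              reac = fill(reac, defaults$reac), ther = fill(ther, defaults$ther),
              outc = fill(outc, defaults$outc), indi = fill(indi, defaults$indi),
              deleted = deleted)
  for (col in c("fda_dt", "event_dt")) {
    data.table::set(raw$demo, j = col,
                    value = faersignal:::normalize_faers_date(raw$demo[[col]]))
  }
  data.table::set(raw$ther, j = "start_dt",
                  value = faersignal:::normalize_faers_date(raw$ther$start_dt))
  structure(raw, class = "faers_raw", counters = list())
}

# ten-report fixture: reports R1..R3 carry the target drug (R3 only as
# concomitant), R4..R10 background drugs; 9/10 reports have outcome codes
fixture_raw <- function() {
  caseid <- as.character(5001:5010)
  pid <- paste0(caseid, "1")
  demo <- data.table::data.table(
    primaryid = pid, caseid = caseid,
    fda_dt = c("20220301", "20220415", "20220601", "20220620", "20220711",
               "20220802", "20220915", "20221001", "20221102", "20221203"),
    event_dt = c("20220115", "20220310", "", "202205", "20220615",
                 "20220701", "20220820", "20220910", "20221005", "20221101"),
    age = c("45", "660", "", "72", "55", "61", "", "38", "29", "80"),
    age_cod = c("YR", "MON", "", "YR", "YR", "YR", "", "YR", "YR", "YR"),
    sex = c("F", "F", "M", "F", "F", "", "F", "M", "F", "F"),
    occp_cod = c("MD", "PH", "CN", "MD", "MD", "", "PH", "MD", "CN", "MD"),
    reporter_country = c("US", "FR", "US", "CA", "US", "DE", "US", "FR", "US", "IT"),
    occr_country = c("US", "FR", "US", "CA", "US", "DE", "US", "FR", "US", "IT")
  )
  drug <- data.table::data.table(
    primaryid = c(pid[1], pid[1], pid[2], pid[3], pid[4:10]),
    drug_seq = c("1", "2", "1", "1", rep("1", 7)),
    role_cod = c("PS", "C", "PS", "C", rep("PS", 7)),
    drugname = c("TRODELVY", "DRUG_001", "Sacituzumab Govitecan", "OTHERMED",
                 paste0("DRUG_", sprintf("%03d", 2:8))),
    prod_ai = c("SACITUZUMAB GOVITECAN-HZIY", "", "SACITUZUMAB GOVITECAN-HZIY",
                "SACITUZUMAB GOVITECAN-HZIY", rep("", 7))
  )
  reac <- data.table::data.table(
    primaryid = c(pid[1], pid[1], pid[2], pid[3], pid[4], pid[5], pid[5],
                  pid[6], pid[7], pid[8], pid[9], pid[10]),
    pt = c("Neutropenia", "Diarrhoea", "Neutropenia", "Anaemia", "Nausea",
           "Neutropenia", "Fatigue", "Diarrhoea", "Nausea", "Headache",
           "Neutropenia", "Rash")
  )
  ther <- data.table::data.table(
    primaryid = c(pid[1], pid[1], pid[2]),
    dsg_drug_seq = c("1", "1", "1"),
    start_dt = c("20220110", "20220103", "20220301")
  )
  outc <- data.table::data.table(
    primaryid = c(pid[1], pid[1], pid[2], pid[3], pid[4], pid[5], pid[6],
                  pid[7], pid[8], pid[9]),
    outc_cod = c("HO", "OT", "DE", "OT", "HO", "LT", "OT", "HO", "OT", "DE")
  )
  indi <- data.table::data.table(
    primaryid = c(pid[1], pid[2]),
    indi_drug_seq = c("1", "1"),
    indi_pt = c("Triple negative breast cancer", "Breast cancer metastatic")
  )
  as_faers_raw(demo, drug, reac, ther, outc, indi)
}

# brute-force deduplication oracle: per CASEID keep latest FDA_DT, ties by
# numerically highest PRIMARYID (straight loop, no shared code)
oracle_dedup_ids <- function(demo) {
  demo <- as.data.frame(demo)
  out <- character(0)
  for (cid in unique(demo$caseid)) {
    rows <- demo[demo$caseid == cid, ]
    key <- as.numeric(rows$fda_dt) * 10^(8 - nchar(rows$fda_dt))
    rows <- rows[key == max(key), ]
    if (nrow(rows) > 1) rows <- rows[which.max(as.numeric(rows$primaryid)), ]
    out <- c(out, rows$primaryid)
  }
  sort(out)
}

# independent odds-ratio-with-CI routine (different composition than the
# implementation: ratio-of-ratios and summed log cells)
oracle_or <- function(a, b, c, d) {
  est <- (a / c) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lg <- log(a) + log(d) - log(b) - log(c)
  list(or = est, lo = exp(lg - 1.96 * se), hi = exp(lg + 1.96 * se))
}

# relative-reporting / PRR oracles via observed and expected proportions
oracle_rrr <- function(a, b, c, d) {
  n <- a + b + c + d
  (a / n) / (((a + b) / n) * ((a + c) / n))
}
oracle_prr <- function(a, b, c, d) {
  p_drug <- a / (a + b)
  p_other <- c / (c + d)
  p_drug / p_other
}
oracle_chi2 <- function(a, b, c, d) {
  # suppress the small-expected-count advisory; the statistic itself is exact
  unname(suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      correct = FALSE)$statistic))
}

# random strictly-positive 2x2 tables for property tests
random_tables <- function(n, max_cell = 60, seed = 1) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, TRUE),
             b = sample.int(max_cell, n, TRUE),
             c = sample.int(max_cell, n, TRUE),
             d = sample.int(max_cell, n, TRUE))
}

write_meddra_fixture <- function(map, path = tempfile(fileext = ".csv")) {
  data.table::fwrite(map, path)
  path
}

# small PT->SOC map covering the fixture PTs
fixture_meddra <- function() {
  data.table::data.table(
    pt = c("Neutropenia", "Anaemia", "Diarrhoea", "Nausea", "Fatigue",
           "Headache", "Rash"),
    soc = c("Blood and lymphatic system disorders",
            "Blood and lymphatic system disorders",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "General disorders", "Nervous system disorders",
            "Skin and subcutaneous tissue disorders")
  )
}

# cohort with hand-picked date situations; all reports are target-exposed
tto_fixture <- function() {
  caseid <- as.character(9001:9007)
  pid <- paste0(caseid, "1")
  demo <- data.table::data.table(
    primaryid = pid, caseid = caseid, fda_dt = "20220901",
    event_dt = c("20220115",  # 14 days after start
                 "20220103",  # before start: negative interval
                 "202201",    # month precision
                 "",          # missing event date
                 "20220214",  # fine, start missing
                 "20220301",  # fine, start partial only
                 "20220110")  # day 0
  )
  drug <- data.table::data.table(primaryid = pid, drug_seq = "1",
                                 role_cod = "PS", drugname = "TRODELVY",
                                 prod_ai = "")
  ther <- data.table::data.table(
    primaryid = pid[c(1, 2, 3, 4, 6, 7)],
    dsg_drug_seq = "1",
    start_dt = c("20220101", "20220110", "20220101", "20220101",
                 "202202", "20220110")
  )
  reac <- data.table::data.table(
    primaryid = pid[c(1, 1, 2, 3, 4, 5, 6, 7)],
    pt = c("Neutropenia", "Diarrhoea", "Neutropenia", "Anaemia",
           "Neutropenia", "Nausea", "Diarrhoea", "Neutropenia")
  )
  build_cohort(as_faers_raw(demo, drug, reac, ther), TARGET_PATTERNS)
}
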