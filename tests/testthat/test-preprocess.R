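test_that("deleted cases are removed; absent deleted ids are a counted no-op", {
  raw <- fixture_raw()
  expect_equal(nrow(drop_deleted(raw)$demo), 10L)   # empty list: identity

  raw$deleted <- c("5001", "5004", "9999")          # 9999 not in the data
  out <- drop_deleted(raw)
  expect_equal(nrow(out$demo), 8L)
  expect_false(any(out$demo$caseid %in% c("5001", "5004")))
  # child rows of removed reports go with them
  expect_false(any(out$reac$primaryid %in% c("50011", "50041")))
  ctr <- attr(out, "counters")
  expect_equal(ctr$deleted_removed, 2L)
  expect_equal(ctr$deleted_unmatched, 1L)
})

test_that("deduplication keeps latest FDA_DT, ties broken by highest PRIMARYID", {
  demo <- data.table::data.table(
    primaryid = c("1001", "1002", "100", "200", "3001"),
    caseid    = c("X",    "X",    "Y",   "Y",   "Z"),
    fda_dt    = c("20220101", "20220301", "20220501", "20220501", "20220601")
  )
  raw <- as_faers_raw(demo = demo)
  out <- deduplicate_reports(raw)
  expect_setequal(out$demo$primaryid, c("1002", "200", "3001"))
  # idempotence
  out2 <- deduplicate_reports(out)
  expect_equal(as.data.frame(out2$demo), as.data.frame(out$demo))
})

test_that("deduplication matches a brute-force oracle on random versioned data", {
  set.seed(11)
  for (rep in 1:5) {
    n_case <- 40
    k <- sample(1:4, n_case, replace = TRUE)
    demo <- data.table::data.table(
      caseid = rep(sprintf("C%02d", seq_len(n_case)), k)
    )
    demo[, primaryid := as.character(sample(seq_len(.N) * 7))]
    # coarse date grid so FDA_DT ties actually occur
    demo[, fda_dt := sprintf("202201%02d", sample(1:5, .N, replace = TRUE))]
    raw <- as_faers_raw(demo = demo)
    out <- deduplicate_reports(raw)
    expect_equal(sort(out$demo$primaryid), oracle_dedup_ids(demo))
    expect_equal(nrow(out$demo), n_case)
  }
})

test_that("duplicate-free data passes through deduplication unchanged", {
  raw <- fixture_raw()
  out <- deduplicate_reports(raw)
  expect_setequal(out$demo$primaryid, raw$demo$primaryid)
})

test_that("cohort flags primary-suspect target exposure only", {
  cohort <- build_cohort(fixture_raw(), TARGET_PATTERNS)
  expect_equal(nrow(cohort), 10L)
  tg <- cohort[cohort$is_target_ps, ]
  # R1 via DRUGNAME=TRODELVY/PS, R2 via DRUGNAME substring/PS;
  # R3 matches PROD_AI but role C, so it is out
  expect_setequal(tg$caseid, c("5001", "5002"))
  # earliest full-precision START_DT among matching PS rows
  expect_equal(tg$target_start_dt[tg$caseid == "5001"], "20220103")
  expect_equal(tg$target_start_dt[tg$caseid == "5002"], "20220301")
  # every target report has at least one matching PS drug row
  expect_true(all(vapply(tg$caseid, function(cid) {
    rows <- fixture_raw()$drug[primaryid == paste0(cid, "1")]
    any(rows$role_cod == "PS" &
          (grepl("TRODELVY", toupper(rows$drugname), fixed = TRUE) |
             grepl("SACITUZUMAB", toupper(paste(rows$drugname, rows$prod_ai)))))
  }, TRUE)))
})

test_that("seriousness follows the outcome-code definition", {
  expect_true(classify_seriousness(c("HO", "OT"))$serious)
  expect_equal(classify_seriousness(c("HO", "OT"))$tally[["HO"]], 1L)
  expect_equal(classify_seriousness(c("HO", "OT"))$tally[["OT"]], 1L)
  expect_false(classify_seriousness(character(0))$serious)
  s <- classify_seriousness(c("HO", "XX"))
  expect_true(s$serious)
  expect_equal(s$tally[["unknown"]], 1L)

  # 9 of 10 fixture reports carry a code
  cohort <- build_cohort(fixture_raw(), TARGET_PATTERNS)
  expect_equal(sum(cohort$serious), 9L)
})

test_that("age conversion uses the unit code and drops unknown units", {
  expect_equal(age_in_years(c("60", "660", "104.28", "730.5"),
                            c("YR", "MON", "WK", "DY")),
               c(60, 55, 2, 2))
  expect_true(is.na(age_in_years("6", "DEC")))
  expect_true(is.na(age_in_years("60", "")))
})
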