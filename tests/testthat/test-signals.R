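# full set of statistics via the public scalar API
.all_stats <- function(a, b, c, d) {
  t <- contingency(a, b, c, d)
  c(ror(t), prr(t), bcpnn_ic(t), ebgm(t))
}

# cohort fixture for contingency counting: 2 target reports with event E,
# 1 target without, 2 non-target with E, 1 non-target without
contingency_fixture <- function() {
  demo <- data.table::data.table(
    primaryid = paste0(700 + 1:6, "1"), caseid = as.character(700 + 1:6),
    fda_dt = rep("20220601", 6)
  )
  drug <- data.table::data.table(
    primaryid = demo$primaryid, drug_seq = "1",
    role_cod = "PS",
    drugname = c("TRODELVY", "TRODELVY", "TRODELVY",
                 "DRUG_A", "DRUG_B", "DRUG_C"),
    prod_ai = ""
  )
  reac <- data.table::data.table(
    primaryid = demo$primaryid[c(1, 2, 3, 4, 5, 6)],
    pt = c("Event E", "Event E", "Other thing", "Event E", "Event E",
           "Something else")
  )
  build_cohort(as_faers_raw(demo, drug, reac), TARGET_PATTERNS)
}

test_that("contingency cells count reports, not rows", {
  cohort <- contingency_fixture()
  t <- build_contingency(cohort, "Event E", "pt")
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 2, b = 1, c = 2, d = 1))
  expect_equal(t$n, 6)
})

test_that("a report with several PTs in one SOC counts once at SOC level", {
  demo <- data.table::data.table(primaryid = c("8011", "8021"),
                                 caseid = c("801", "802"),
                                 fda_dt = "20220601")
  drug <- data.table::data.table(primaryid = demo$primaryid, drug_seq = "1",
                                 role_cod = "PS",
                                 drugname = c("TRODELVY", "DRUG_A"),
                                 prod_ai = "")
  reac <- data.table::data.table(primaryid = c("8011", "8011", "8021"),
                                 pt = c("Neutropenia", "Anaemia", "Nausea"))
  cohort <- build_cohort(as_faers_raw(demo, drug, reac), TARGET_PATTERNS)
  map <- load_meddra_map(write_meddra_fixture(fixture_meddra()))
  t <- build_contingency(cohort, "Blood and lymphatic system disorders",
                         "soc", meddra = map)
  expect_equal(t$a, 1)   # one report, despite two blood PTs
})

test_that("degenerate margins give undefined estimates, not errors", {
  cohort <- contingency_fixture()[is_target_ps == TRUE]  # no non-target reports
  t <- build_contingency(cohort, "Event E", "pt")
  expect_equal(t$c + t$d, 0)
  expect_true(is.na(ror(t)$ror))
  expect_true(is.na(prr(t)$prr))
})

test_that("ROR point estimate and CI match the stated formula", {
  expect_equal(ror(contingency(50, 50, 50, 50))$ror, 1)
  t <- contingency(10, 20, 30, 40)
  o <- oracle_or(10, 20, 30, 40)
  r <- ror(t)
  expect_equal(r$ror, o$or, tolerance = 1e-12)
  expect_equal(r$ci_low, o$lo, tolerance = 1e-12)
  expect_equal(r$ci_high, o$hi, tolerance = 1e-12)
  expect_equal(r$ror, 2 / 3, tolerance = 1e-12)
  # zero cell: undefined, no continuity correction
  z <- ror(contingency(3, 0, 5, 10))
  expect_true(is.na(z$ror) && is.na(z$ci_low))
})

test_that("PRR and uncorrected chi-squared match hand values and chisq.test", {
  ind <- contingency(9, 21, 21, 49)   # a = (a+b)(a+c)/n
  expect_equal(prr(ind)$prr, 1)
  expect_equal(prr(ind)$chi2, 0)

  t <- contingency(10, 20, 30, 40)
  expect_equal(prr(t)$prr, 7 / 9, tolerance = 1e-12)
  expect_equal(prr(t)$chi2, oracle_chi2(10, 20, 30, 40), tolerance = 1e-10)
  expect_equal(round(prr(t)$chi2, 4), 0.7937)

  t2 <- contingency(30, 10, 10, 50)
  expect_equal(prr(t2)$prr, 4.5, tolerance = 1e-12)
  expect_equal(prr(t2)$chi2, oracle_chi2(30, 10, 10, 50), tolerance = 1e-10)
  s2 <- .all_stats(30, 10, 10, 50)
  fl <- evaluate_criteria(data.frame(a = 30, ror_low = s2$ci_low,
                                     prr = s2$prr, chi2 = s2$chi2,
                                     ic025 = s2$ic025, ebgm05 = s2$ebgm05))
  expect_true(fl$prr_pos)
})

test_that("information component: point value, shrinkage moments, limits", {
  ind <- contingency(9, 21, 21, 49)
  expect_equal(bcpnn_ic(ind)$ic, 0)

  t <- contingency(10, 20, 30, 40)
  b <- bcpnn_ic(t)
  expect_equal(b$ic, log2(10 * 100 / (30 * 40)), tolerance = 1e-12)
  expect_equal(round(b$ic, 3), -0.263)
  # independent evaluation of the closed forms (different arrangement)
  p <- bcpnn_priors()
  n <- 100; ab <- 30; ac <- 40
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((ab + p$alpha1) * (ac + p$beta1))
  e_ref <- (log((10 + p$gamma11)) + log(n + p$alpha) + log(n + p$beta) -
              log(n + gamma) - log(ab + p$alpha1) - log(ac + p$beta1)) / log(2)
  expect_equal(b$ic_e, e_ref, tolerance = 1e-12)
  expect_equal(b$ic025, b$ic_e - 2 * sqrt(b$ic_v), tolerance = 1e-12)

  # large-n limit with fixed ratios: E(IC) -> IC and V(IC) -> 0
  for (scale in c(1e3, 1e4, 1e5)) {
    tt <- contingency(0.1 * scale, 0.2 * scale, 0.3 * scale, 0.4 * scale)
    bb <- bcpnn_ic(tt)
    expect_lt(abs(bb$ic_e - bb$ic), 50 / scale)
    expect_lt(bb$ic_v, 50 / scale)
  }
  # a = 0: shrunken moments still defined, point IC is not
  z <- bcpnn_ic(contingency(0, 10, 10, 80))
  expect_true(is.na(z$ic))
  expect_true(is.finite(z$ic_e) && is.finite(z$ic025))
})

test_that("EBGM closed form, bounds, and the log2 identity with IC", {
  expect_equal(ebgm(contingency(9, 21, 21, 49))$ebgm, 1)
  t <- contingency(10, 20, 30, 40)
  e <- ebgm(t)
  expect_equal(e$ebgm, 5 / 6, tolerance = 1e-12)
  expect_equal(e$ebgm, oracle_rrr(10, 20, 30, 40), tolerance = 1e-12)
  expect_lt(e$ebgm05, e$ebgm)
  expect_gt(e$ebgm95, e$ebgm)
  for (i in 1:50) {
    tab <- random_tables(1, seed = i)
    tt <- contingency(tab$a, tab$b, tab$c, tab$d)
    expect_equal(bcpnn_ic(tt)$ic, log2(ebgm(tt)$ebgm), tolerance = 1e-12)
  }
})

test_that("criteria flags and consensus follow the four-algorithm thresholds", {
  # published SOC-level row: strong blood-dyscrasia signal
  strong <- data.frame(a = 549, ror_low = 6.58, prr = 6.65, chi2 = 2662.35,
                       ic025 = 2.59, ebgm05 = 6.08)
  expect_true(evaluate_criteria(strong)$consensus)
  # ROR CI crossing 1 vetoes consensus regardless of the rest
  weak <- data.frame(a = 261, ror_low = 0.68, prr = 0.78, chi2 = 17.91,
                     ic025 = -0.55, ebgm05 = 0.69)
  expect_false(evaluate_criteria(weak)$consensus)
  # a >= 3 rule beats an enormous ROR
  tiny <- data.frame(a = 2, ror_low = 50, prr = 100, chi2 = 500,
                     ic025 = 5, ebgm05 = 40)
  fl <- evaluate_criteria(tiny)
  expect_true(fl$ror_pos && fl$prr_pos)
  expect_false(fl$min_count_ok)
  expect_false(fl$consensus)
  # undefined estimates fail their criterion
  und <- data.frame(a = 5, ror_low = NA, prr = 3, chi2 = 10, ic025 = 1,
                    ebgm05 = 3)
  expect_false(evaluate_criteria(und)$ror_pos)
})

test_that("all four statistics cross the null together (ad vs bc)", {
  tabs <- random_tables(400, seed = 5)
  tabs <- tabs[tabs$a * tabs$d != tabs$b * tabs$c, ]
  for (i in seq_len(nrow(tabs))) {
    s <- .all_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    up <- tabs$a[i] * tabs$d[i] > tabs$b[i] * tabs$c[i]
    expect_equal(s$ror > 1, up)
    expect_equal(s$prr > 1, up)
    expect_equal(s$ebgm > 1, up)
    expect_equal(s$ic > 0, up)
  }
})

test_that("increasing a with b, c, d fixed strictly increases every estimate", {
  prev <- .all_stats(3, 20, 30, 200)
  for (a in c(5, 9, 16, 30)) {
    cur <- .all_stats(a, 20, 30, 200)
    expect_gt(cur$ror, prev$ror)
    expect_gt(cur$prr, prev$prr)
    expect_gt(cur$ebgm, prev$ebgm)
    expect_gt(cur$ic, prev$ic)
    prev <- cur
  }
})

test_that("screening output is ordered, flagged, and respects SOC exclusions", {
  cfg <- synthetic_config(n_reports = 8000, seed = 31)
  raw <- simulate_raw(cfg)
  cohort <- build_cohort(deduplicate_reports(drop_deleted(raw)),
                         TARGET_PATTERNS)
  map_path <- write_meddra_fixture(synthetic_pt_soc(cfg))
  map <- load_meddra_map(map_path)

  sig <- screen_signals(cohort, "pt", map)
  expect_true(all(sig$a >= 1))
  expect_true(!is.unsorted(-sig$a))
  expect_true(all(sig$consensus ==
                    (sig$ror_pos & sig$prr_pos & sig$bcpnn_pos &
                       sig$mgps_pos & sig$min_count_ok)))
  # CI brackets the estimate whenever defined
  ok <- !is.na(sig$ror)
  expect_true(all(sig$ror_low[ok] <= sig$ror[ok] &
                    sig$ror[ok] <= sig$ror_high[ok]))

  # excluding the SOC that holds a planted PT removes it from the consensus
  # report but keeps it, flagged, in the raw output
  planted_soc <- map_pt_to_soc(map, "PT_001")
  sig_ex <- screen_signals(cohort, "pt", map, soc_exclusions = planted_soc)
  expect_true(any(sig_ex$excluded))
  expect_false("PT_001" %in% consensus_report(sig_ex)$event)
  expect_true("PT_001" %in% sig_ex$event)
})

test_that("null data (no planted signals) yields almost no consensus calls", {
  counts <- integer(0)
  for (s in 1:3) {
    cfg <- synthetic_config(n_reports = 10000,
                            planted = data.frame(pt = "PT_001", rr = 1),
                            seed = 400 + s)
    cohort <- build_cohort(deduplicate_reports(drop_deleted(simulate_raw(cfg))),
                           TARGET_PATTERNS)
    counts <- c(counts, sum(screen_signals(cohort, "pt")$consensus))
  }
  expect_lte(mean(counts), 2)
})
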