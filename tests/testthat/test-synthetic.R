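test_that("fixed seed reproduces byte-identical quarters", {
  cfg <- synthetic_config(n_reports = 500, seed = 9)
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  simulate_quarter(cfg, d1)
  simulate_quarter(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated quarters honour the declared relational structure", {
  cfg <- synthetic_config(n_reports = 2000, seed = 12)
  raw <- simulate_raw(cfg)
  # every child row keys back to a demo row
  ids <- unique(raw$demo$primaryid)
  for (tb in c("drug", "reac", "ther", "outc", "indi")) {
    expect_true(all(raw[[tb]]$primaryid %in% ids), info = tb)
  }
  # duplicates: strictly more demo rows than cases, bookkeeping matches
  gt <- attr(raw, "ground_truth")
  expect_equal(nrow(raw$demo), cfg$n_reports + gt$n_duplicates)
  expect_equal(length(raw$deleted), gt$n_deleted)
})

test_that("configured duplicate fraction is exactly what dedup removes", {
  cfg <- synthetic_config(n_reports = 10000, dup_fraction = 0.1, seed = 3)
  raw <- simulate_raw(cfg)
  dedup <- deduplicate_reports(raw)
  removed <- nrow(raw$demo) - nrow(dedup$demo)
  expect_equal(removed, 1000L)
  # surviving version per duplicated case is the latest / highest
  expect_equal(sort(unique(dedup$demo$caseid)), sort(raw$demo$caseid[
    !duplicated(raw$demo$caseid)]))
})

test_that("pipeline round-trip recovers n_reports * (1 - deleted) unique cases", {
  cfg <- synthetic_config(n_reports = 3000, deleted_fraction = 0.01, seed = 21)
  dir <- tempfile("sim")
  simulate_quarter(cfg, dir)
  raw <- read_faers_quarter(dir)
  clean <- deduplicate_reports(drop_deleted(raw))
  expect_equal(length(unique(clean$demo$caseid)), as.integer(3000 * 0.99))
  expect_equal(nrow(clean$demo), as.integer(3000 * 0.99))
})

test_that("expected tables are exact in the null and bound the observed counts", {
  # R = 1 everywhere: expected EBGM of the expected table is exactly 1
  cfg0 <- synthetic_config(n_reports = 5000,
                           planted = data.frame(pt = "PT_010", rr = 1),
                           seed = 77)
  et0 <- expected_table(cfg0, "PT_010")
  expect_equal(ebgm(et0)$ebgm, 1, tolerance = 1e-12)

  # planted R = 10 at 2% prevalence: observed a within 3*sqrt(expected a)
  cfg <- synthetic_config(n_reports = 30000, seed = 8)
  raw <- simulate_raw(cfg)
  cohort <- build_cohort(deduplicate_reports(drop_deleted(raw)),
                         TARGET_PATTERNS)
  for (p in attr(raw, "ground_truth")$planted$pt) {
    et <- expected_table(cfg, p)
    t_obs <- build_contingency(cohort, p, "pt")
    expect_lt(abs(t_obs$a - et$a), 3 * sqrt(et$a))
  }

  # zero prevalence: no target exposure at all
  cfg_z <- synthetic_config(n_reports = 1000, target_prevalence = 0, seed = 5)
  et_z <- expected_table(cfg_z, "PT_001")
  expect_equal(et_z$a + et_z$b, 0)
  raw_z <- simulate_raw(cfg_z)
  cohort_z <- build_cohort(raw_z, TARGET_PATTERNS)
  expect_equal(sum(cohort_z$is_target_ps), 0L)
})

test_that("EBGM recovers the planted relative rate within 15%, 20 seeds", {
  # mild-saturation conditions: one planted PT among near-uniform events and
  # few events per report, so the per-report probability ratio EBGM estimates
  # sits close to the planted per-draw rate R (see the methods vignette for
  # why heavy planting attenuates it further)
  vals <- numeric(0)
  n_obs <- numeric(0)
  for (s in 1:20) {
    cfg <- synthetic_config(n_reports = 50000, n_background_pts = 100,
                            dirichlet_conc = 50, events_lambda = 0.5,
                            planted = data.frame(pt = "PT_050", rr = 5),
                            seed = 600 + s)
    cohort <- build_cohort(deduplicate_reports(drop_deleted(simulate_raw(cfg))),
                           TARGET_PATTERNS)
    t <- build_contingency(cohort, "PT_050", "pt")
    vals <- c(vals, ebgm(t)$ebgm)
    n_obs <- c(n_obs, t$a)
  }
  expect_gte(mean(n_obs), 50)
  expect_lt(abs(mean(vals) - 5) / 5, 0.15)
  # and the closed-form expectation pins the attenuated estimand exactly
  et <- expected_table(cfg, "PT_050")
  expect_lt(abs(mean(vals) - ebgm(et)$ebgm) / ebgm(et)$ebgm, 0.10)
})

test_that("planting a PT outside the universe is a configuration error", {
  expect_error(synthetic_config(planted = data.frame(pt = "NOT_A_PT", rr = 5)),
               "universe")
})
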