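# End-to-end orchestration: ingest -> drop deleted -> dedup -> cohort ->
# descriptives / signal screening / time-to-onset, with per-stage counts
# logged so any run is self-documenting.

#' Pipeline configuration
#'
#' @param input_dirs Character vector of quarter directories.
#' @param patterns Drug-name patterns (substring, case-insensitive) matched
#'   against DRUGNAME and PROD_AI.
#' @param meddra_path Path to the two-column PT-to-SOC map.
#' @param soc_exclusions SOC names excluded from consensus reporting.
#' @param min_a Minimum report count criterion (default 3).
#' @param top_k Categories listed in the descriptive table.
#' @param out_dir Output directory for the TSV bundle.
#' @param dialect A [faers_dialect()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dirs, patterns, meddra_path,
                            soc_exclusions = character(0), min_a = 3,
                            top_k = 5, out_dir = ".",
                            dialect = faers_dialect()) {
  stopifnot(length(input_dirs) >= 1L, length(patterns) >= 1L)
  structure(list(input_dirs = input_dirs, patterns = patterns,
                 meddra_path = meddra_path, soc_exclusions = soc_exclusions,
                 min_a = min_a, top_k = top_k, out_dir = out_dir,
                 dialect = dialect),
            class = "pipeline_config")
}

# concatenate several quarters into one faers_raw
.bind_quarters <- function(raws) {
  if (length(raws) == 1L) return(raws[[1L]])
  out <- raws[[1L]]
  for (tb in c("demo", "drug", "reac", "ther", "outc", "indi")) {
    out[[tb]] <- data.table::rbindlist(lapply(raws, `[[`, tb))
  }
  out$deleted <- unique(unlist(lapply(raws, `[[`, "deleted")))
  out
}

#' Run the full screening pipeline
#'
#' Reads the configured quarters, removes deleted cases, deduplicates
#' report versions, builds the primary-suspect cohort, and writes
#' `table2.tsv` (descriptives), `signals_soc.tsv`, `signals_pt.tsv`,
#' `tto.tsv`, and `run_log.txt` under `config$out_dir`. Any stage failure
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the cohort, both screening tables, the
#'   per-PT onset table, the descriptive summary and the stage `counts`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  raws <- stage("ingest", lapply(config$input_dirs, read_faers_quarter,
                                 dialect = config$dialect))
  raw <- .bind_quarters(raws)
  counts <- c(raw_reports = nrow(raw$demo))
  raw <- stage("drop_deleted", drop_deleted(raw))
  counts["after_deleted"] <- nrow(raw$demo)
  raw <- stage("deduplicate", deduplicate_reports(raw))
  counts["after_dedup"] <- nrow(raw$demo)
  cohort <- stage("cohort", build_cohort(raw, config$patterns))
  counts["cohort_target"] <- sum(cohort$is_target_ps)
  meddra <- stage("meddra", load_meddra_map(config$meddra_path))

  tab2 <- stage("descriptives", summarize_cohort(cohort, top_k = config$top_k))
  sig_soc <- stage("signals_soc",
                   screen_signals(cohort, "soc", meddra,
                                  soc_exclusions = config$soc_exclusions,
                                  min_a = config$min_a))
  sig_pt <- stage("signals_pt",
                  screen_signals(cohort, "pt", meddra,
                                 soc_exclusions = config$soc_exclusions,
                                 min_a = config$min_a))
  onset <- stage("tto", compute_onset_by_pt(cohort))
  tto_tab <- tto_by_pt(onset, min_n = 3)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) data.table::fwrite(x, file.path(config$out_dir, f),
                                          sep = "\t")
  wr(tab2, "table2.tsv")
  wr(.format_signal_tsv(sig_soc), "signals_soc.tsv")
  wr(.format_signal_tsv(sig_pt), "signals_pt.tsv")
  wr(tto_tab, "tto.tsv")
  log_lines <- c(
    sprintf("faersignal pipeline run %s", format(Sys.time(), "%Y-%m-%d")),
    sprintf("quarters: %s", paste(config$input_dirs, collapse = ", ")),
    sprintf("patterns: %s", paste(config$patterns, collapse = " | ")),
    sprintf("min_a: %d; excluded SOCs: %s", config$min_a,
            paste(config$soc_exclusions, collapse = ", ")),
    sprintf("%s: %d", names(counts), counts)
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, table2 = tab2, signals_soc = sig_soc,
                 signals_pt = sig_pt, tto = tto_tab, counts = counts))
}

# stable human-readable layout mirroring published signal tables
.format_signal_tsv <- function(sig) {
  f <- function(x) ifelse(is.na(x), "-", formatC(x, format = "f", digits = 2))
  data.table::data.table(
    event = sig$event, soc = sig$soc, n = sig$a,
    ror_ci = sprintf("%s (%s-%s)", f(sig$ror), f(sig$ror_low), f(sig$ror_high)),
    prr_chi2 = sprintf("%s (%s)", f(sig$prr), f(sig$chi2)),
    ic_ic025 = sprintf("%s (%s)", f(sig$ic), f(sig$ic025)),
    ebgm_ebgm05 = sprintf("%s (%s)", f(sig$ebgm), f(sig$ebgm05)),
    consensus = sig$consensus, excluded = sig$excluded
  )
}
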