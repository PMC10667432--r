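#!/usr/bin/env Rscript
# Step 3: demographic / clinical description of the target cohort — sex,
# age bands, indications, seriousness and outcome codes, reporting years,
# countries, reporter occupations, and onset-day bins, each as count and
# percentage of all target reports.

suppressMessages(library(faersignal))

if (!file.exists("scratch/cohort.rds")) stop("run analysis/02_preprocess.R first")
cohort <- readRDS("scratch/cohort.rds")

summary_tab <- summarize_cohort(cohort, top_k = 5)
data.table::fwrite(summary_tab, "results/cohort_summary.tsv", sep = "\t")

cat(sprintf("Target cohort: %d reports\n", attr(summary_tab, "total_reports")))
for (sec in c("sex", "seriousness", "time_to_onset")) {
  cat("\n--", sec, "--\n")
  print(summary_tab[summary_tab$section == sec,
                    c("category", "n", "pct")])
}
cat("\nFull table written to results/cohort_summary.tsv\n")
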