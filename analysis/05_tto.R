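#!/usr/bin/env Rscript
# Step 5: time-to-onset analysis. Overall summary (per report) plus the
# per-PT median/IQR table (per report-event pair), with the exclusion
# accounting that partitions the cohort.

suppressMessages(library(faersignal))

if (!file.exists("scratch/cohort.rds")) stop("run analysis/02_preprocess.R first")
cohort <- readRDS("scratch/cohort.rds")

obs <- compute_onset(cohort)
s <- summarize_tto(obs)
overall <- data.table::data.table(
  metric = c("n_with_onset", names(s$n_excluded), "mean", "median", "q1", "q3",
             s$bins$label),
  value = c(s$n_with_onset, unname(s$n_excluded), round(s$mean, 2), s$median,
            s$q1, s$q3, s$bins$n)
)
data.table::fwrite(overall, "results/tto_overall.tsv", sep = "\t")

by_pt <- tto_by_pt(compute_onset_by_pt(cohort), min_n = 10)
data.table::fwrite(by_pt, "results/tto_by_pt.tsv", sep = "\t")

cat(sprintf("Onset evaluable for %d of %d target reports\n",
            s$n_with_onset, nrow(obs)))
cat(sprintf("  excluded: %s\n",
            paste(names(s$n_excluded), s$n_excluded, collapse = ", ")))
cat(sprintf("  median %s days (IQR %s-%s), mean %.1f\n",
            s$median, s$q1, s$q3, s$mean))
cat("\nPer-PT onset (n >= 10):\n")
print(by_pt)
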