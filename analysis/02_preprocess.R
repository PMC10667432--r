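#!/usr/bin/env Rscript
# Step 2: ingest -> drop deleted cases -> deduplicate versions -> build the
# primary-suspect cohort. Stage counts go to results/stage_counts.tsv; the
# cohort object is cached under scratch/ for the later steps.

suppressMessages(library(faersignal))

sim_dir <- "scratch/sim_q1"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

patterns <- c("sacituzumab govitecan", "trodelvy")

raw <- read_faers_quarter(sim_dir)
counts <- data.table::data.table(stage = "raw_reports", n = nrow(raw$demo))
raw <- drop_deleted(raw)
counts <- rbind(counts, list("after_deleted", nrow(raw$demo)))
raw <- deduplicate_reports(raw)
counts <- rbind(counts, list("after_dedup", nrow(raw$demo)))

cohort <- build_cohort(raw, patterns)
counts <- rbind(counts, list("cohort_target", sum(cohort$is_target_ps)))

data.table::fwrite(counts, "results/stage_counts.tsv", sep = "\t")
saveRDS(cohort, "scratch/cohort.rds")

cat("Stage counts (each stage can only shrink the data):\n")
print(counts)
cat(sprintf("Target cohort: %d of %d deduplicated reports (%.2f%%)\n",
            sum(cohort$is_target_ps), nrow(cohort),
            100 * mean(cohort$is_target_ps)))
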