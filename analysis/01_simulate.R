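#!/usr/bin/env Rscript
# Step 1: generate the synthetic FAERS-like study data.
#
# One quarter at the reference conditions — 50,000 reports, 2% target-drug
# prevalence, three planted PTs at relative reporting rate 10, realistic
# duplication/deletion/date-missingness — written as $-delimited ASCII
# exactly as the ingest step expects to read it. Ground truth (planted PTs
# and their expected report counts) is written alongside for later checks.

suppressMessages(library(faersignal))

seed <- 1L
sim_dir <- "scratch/sim_q1"
dir.create("scratch", showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
sim <- simulate_quarter(cfg, sim_dir)

truth <- data.table::fread(sim$truth_path)
cat("Simulated quarter in", sim_dir, "\n")
cat(sprintf("  %d cases (+%d duplicate versions, %d deleted)\n",
            cfg$n_reports, attr(sim$raw, "ground_truth")$n_duplicates,
            attr(sim$raw, "ground_truth")$n_deleted))
cat("  planted signals (expected a = target reports carrying the PT):\n")
print(truth)
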