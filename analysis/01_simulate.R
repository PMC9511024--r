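#!/usr/bin/env Rscript
# Generate the study cohort: 19 healthy controls and 19 patients (4
# non-irradiated, 5 whole-ventricular RT, 2 supratentorial focal RT, 4
# low-dose and 4 high-dose whole-brain RT), each with a 132-parcel,
# 125-timepoint TR = 4 s BOLD acquisition, confound tables and clinical
# covariates. Everything is written as plain text under results/cohort/.

suppressMessages(library(connvar))

seed <- 20260925L
cfg <- cohort_config(seed = seed)
cat("Simulating cohort:\n")
print(cfg)
co <- simulate_cohort(cfg)
write_cohort(co, "results/cohort")

rec <- co$records
cat(sprintf("\n%d subjects written to results/cohort/\n", nrow(rec)))
cat(sprintf("patients with missing CMB counts: %d (poor SWI stand-in)\n",
            sum(is.na(rec$cmb_count) & rec$group != "healthy-control")))
cat(sprintf("memory z-score range: [%.2f, %.2f]\n",
            min(rec$isl_zscore), max(rec$isl_zscore)))
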