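#!/usr/bin/env Rscript
# Simulate the default grade-stratified cohort (8/21/20 tumors, mirroring a
# consecutive breast-carcinoma series) and write the measured and
# ground-truth tables.

suppressMessages(library(prolifsim))
dir.create("results", showWarnings = FALSE)

seed <- 1L
cfg <- cohort_config()
cohort <- simulate_cohort(cfg, seed = seed)
write_cohort(cohort, "results/cohort_measured.csv", "results/cohort_truth.csv")
cat("wrote results/cohort_measured.csv + cohort_truth.csv (",
    nrow(cohort), "tumors, seed", seed, ")\n\n")

s <- grade_summary(cohort)
cat("Per-grade mean +/- sd:\n")
for (i in seq_len(nrow(s))) {
  cat(sprintf("  grade %-7s n=%2d  MIB-1/field %7.1f +/- %6.1f   PhH3/field %6.2f +/- %5.2f\n",
              s$group[i], s$n[i], s$mib1_per_field_mean[i], s$mib1_per_field_sd[i],
              s$phh3_per_field_mean[i], s$phh3_per_field_sd[i]))
  cat(sprintf("  %13s mitoses/10HPF %6.1f +/- %5.1f   nuclear IOD %7.0f +/- %5.0f\n",
              "", s$mitoses_per_10hpf_mean[i], s$mitoses_per_10hpf_sd[i],
              s$iod_mean[i], s$iod_sd[i]))
}
write.csv(s, "results/grade_summary.csv", row.names = FALSE)
cat("\nwrote results/grade_summary.csv\n")
cat("High-grade tumors carry higher counts on every marker and higher IOD,\n")
cat("with ground-truth interphase durations (cohort_truth.csv) available for\n")
cat("the model comparison in 05_model_comparison.R.\n")
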