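#!/usr/bin/env Rscript
# Test the decoupling model against the simulated measurements: does the
# observed per-tumor PhH3/MIB-1 ratio track T_m/(T_m + T_i), and does
# cycle-duration decoupling reproduce the characteristic correlation
# ordering (same-window markers strongest, MIB-1 weaker, IOD weakest but
# closest to MIB-1) across replicate cohorts?
# Run 02_simulate_cohort.R first.

suppressMessages(library(prolifsim))
stopifnot(file.exists("results/cohort_measured.csv"))
cohort <- read_cohort("results/cohort_measured.csv", "results/cohort_truth.csv")

mc <- compare_to_model(cohort)
write.csv(mc, "results/model_comparison.csv", row.names = FALSE)
mare <- mean(abs(mc$relative_error), na.rm = TRUE)
cat(sprintf("Per-tumor observed PhH3/MIB-1 vs predicted T_m/(T_m + T_i):\n"))
cat(sprintf("  mean |relative error| = %.1f%%   Spearman rank correlation = %.2f\n",
            100 * mare, attr(mc, "rank_correlation")))
cat("  (the +5% systematic piece reflects the MIB-1 sensitivity of 0.95;\n")
cat("   the rest is Poisson counting noise)\n")
cat("wrote results/model_comparison.csv\n\n")

# replicate experiment: correlation structure across seeded cohorts
reps <- 50L
cfg <- cohort_config()
res <- vapply(seq_len(reps), function(r) {
  cm <- correlation_matrix(simulate_cohort(cfg, seed = 100 + r))
  c(mit_phh3 = cm["mitoses_per_10hpf", "phh3_per_field"],
    mib1_phh3 = cm["mib1_per_field", "phh3_per_field"],
    mib1_mit = cm["mib1_per_field", "mitoses_per_10hpf"],
    iod_mib1 = cm["iod", "mib1_per_field"],
    iod_phh3 = cm["iod", "phh3_per_field"],
    iod_mit = cm["iod", "mitoses_per_10hpf"])
}, numeric(6))

means <- rowMeans(res)
cat(sprintf("Across %d replicate cohorts (mean r):\n", reps))
cat(sprintf("  r(mitoses, PhH3) = %.3f   <- same staining window\n", means["mit_phh3"]))
cat(sprintf("  r(MIB-1, mitoses) = %.3f, r(MIB-1, PhH3) = %.3f   <- decoupled by T_i spread\n",
            means["mib1_mit"], means["mib1_phh3"]))
cat(sprintf("  r(IOD, MIB-1) = %.3f > r(IOD, PhH3) = %.3f, r(IOD, mitoses) = %.3f\n",
            means["iod_mib1"], means["iod_phh3"], means["iod_mit"]))
cat(sprintf("  same-window pair strongest in %d%% of replicates;\n",
            round(100 * mean(res["mit_phh3", ] > pmax(res["mib1_phh3", ], res["mib1_mit", ])))))
cat(sprintf("  IOD correlates best with MIB-1 in %d%% of replicates.\n",
            round(100 * mean(res["iod_mib1", ] > pmax(res["iod_phh3", ], res["iod_mit", ])))))

summary_tab <- data.frame(pair = names(means), mean_r = as.numeric(means),
                          sd_r = apply(res, 1, sd))
write.csv(summary_tab, "results/correlation_replicates.csv", row.names = FALSE)
cat("wrote results/correlation_replicates.csv\n")
cat("\nInterpretation: MIB-1 integrates the whole cycle, so tumors with\n")
cat("longer interphase (aneuploid, longer S phase; longer cycles in high\n")
cat("grade) show disproportionately high MIB-1 relative to PhH3/mitoses --\n")
cat("the markers decorrelate even though every count is accurate.\n")
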