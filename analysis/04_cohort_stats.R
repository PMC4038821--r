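#!/usr/bin/env Rscript
# The cohort-level statistics on the simulated series: Pearson correlation
# matrix, MIB-1-on-PhH3 regression, above-the-line contingency by grade with
# Fisher's exact test, and pooled t tests of grades 1-2 vs 3.
# Run 02_simulate_cohort.R first.

suppressMessages(library(prolifsim))
stopifnot(file.exists("results/cohort_measured.csv"))
cohort <- read_cohort("results/cohort_measured.csv", "results/cohort_truth.csv")

cm <- correlation_matrix(cohort)
cat("Pearson correlation matrix:\n")
print(round(cm, 2))

fit <- ols_fit(cohort$phh3_per_field, cohort$mib1_per_field)
cat(sprintf("\nRegression: MIB-1 = %.1f x PhH3 + %.0f   (r = %.2f)\n",
            fit$slope, fit$intercept, fit$pearson_r))

cls <- classify_above_line(cohort, fit)
p_fisher <- fisher_exact_2x2(cls$contingency)
for (g in 1:3) {
  n_g <- sum(cohort$grade == g)
  n_above <- sum(cls$above[cohort$grade == g])
  cat(sprintf("  grade %d: %d of %d (%.1f%%) above the regression line\n",
              g, n_above, n_g, 100 * n_above / n_g))
}
cat(sprintf("Above-line, grades 1-2 pooled vs 3: Fisher p = %.2g\n", p_fisher))

cat("\nPooled t tests, grades 1-2 vs grade 3:\n")
low <- cohort$grade %in% c(1, 2)
for (v in c("mib1_per_field", "phh3_per_field", "mitoses_per_10hpf", "iod")) {
  tt <- two_sample_t(cohort[[v]][low], cohort[[v]][!low])
  cat(sprintf("  %-18s t = %6.2f, p = %.2e\n", v, tt$t, tt$p))
}

jsonlite::write_json(
  list(correlations = cm, fit = fit[c("slope", "intercept", "pearson_r")],
       contingency = cls$contingency, fisher_p = p_fisher),
  "results/cohort_stats.json", auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
cat("\nwrote results/cohort_stats.json\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  cohort$grade_f <- factor(cohort$grade)
  p1 <- ggplot(cohort, aes(phh3_per_field, mib1_per_field, shape = grade_f)) +
    geom_point(size = 2) +
    geom_abline(slope = fit$slope, intercept = fit$intercept) +
    labs(x = "PhH3 / 10x field", y = "MIB-1 / 10x field", shape = "grade",
         title = "High-grade tumors sit above the MIB-1 on PhH3 regression") +
    theme_minimal()
  ggsave("results/figures/mib1_vs_phh3.png", p1, width = 6, height = 4.5, dpi = 150)
  p2 <- ggplot(cohort, aes(phh3_per_field, mitoses_per_10hpf, shape = grade_f)) +
    geom_point(size = 2) +
    labs(x = "PhH3 / 10x field", y = "mitoses / 10 HPF", shape = "grade",
         title = "Same-window markers: mitotic count vs PhH3") +
    theme_minimal()
  ggsave("results/figures/mitoses_vs_phh3.png", p2, width = 6, height = 4.5, dpi = 150)
  cat("wrote results/figures/{mib1_vs_phh3,mitoses_vs_phh3}.png\n")
}
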