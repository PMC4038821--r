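#!/usr/bin/env Rscript
# The phase-occupancy decoupling model on its own: the worked ratio examples,
# the full decoupling curve, and the growth-law comparison showing why cycle
# time matters as much as the proliferating fraction.

suppressMessages(library(prolifsim))
dir.create("results", showWarnings = FALSE)

d24 <- cell_cycle_durations(t_g1 = 23, t_s = 0, t_g2 = 0, t_m = 1)
d30 <- cell_cycle_durations(t_g1 = 29.9, t_s = 0, t_g2 = 0, t_m = 1)
cat(sprintf("PhH3/MIB-1 at T_m = 1 h, T_i = 23 h:   %.2f%%\n",
            100 * phh3_mib1_ratio(d24)))
cat(sprintf("PhH3/MIB-1 at T_m = 1 h, T_i = 29.9 h: %.2f%%\n",
            100 * phh3_mib1_ratio(d30)))
cat(sprintf("relative decrease after a 30%% longer interphase: %.1f%%\n",
            100 * relative_ratio_change(d24, d30)))

curve <- decoupling_curve(t_m = 1, t_i_grid = seq(0, 120, by = 0.5))
write.csv(curve, "results/decoupling_curve.csv", row.names = FALSE)
cat("wrote results/decoupling_curve.csv (", nrow(curve), "points )\n")

# growth: tumor A (P = 60%, T_c = 72 h) vs tumor B (P = 20%, T_c = 24 h)
horizons <- c(24, 72, 240, 720)
growth <- data.frame(
  delta_t_hours = horizons,
  tumor_A = sapply(horizons, function(dt) grow(growth_params(1e6, 0.6, dt, 72))),
  tumor_B = sapply(horizons, function(dt) grow(growth_params(1e6, 0.2, dt, 24)))
)
growth$B_over_A <- growth$tumor_B / growth$tumor_A
write.csv(growth, "results/growth_comparison.csv", row.names = FALSE)
cat("\nGrowth from 1e6 cells (B has 3x lower P but 3x shorter cycle):\n")
print(growth, row.names = FALSE)
cat("-> the fast-cycling tumor wins at every horizon: T_c sits in the exponent.\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(curve, aes(t_i_hours, 100 * ratio)) +
    geom_line() +
    annotate("point", x = c(23, 29.9), y = 100 * c(1 / 24, 1 / 30.9)) +
    labs(x = "interphase duration T_i (h)", y = "PhH3/MIB-1 (%)",
         title = "Expected PhH3/MIB-1 ratio falls as interphase lengthens") +
    theme_minimal()
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/decoupling_curve.png", p, width = 6, height = 4, dpi = 150)
  cat("wrote results/figures/decoupling_curve.png\n")
}
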