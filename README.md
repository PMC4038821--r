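# prolifsim

Synthetic benchmarking of tumor proliferation markers under cell-cycle
phase decoupling.

## The problem

Three readouts of tumor proliferation are in routine pathology use, and
they mark different spans of the cell cycle: the manual **mitotic count**
on H&E (mitotic figures over 10 high-power fields), **PhH3**
(phospho-histone H3, staining mitosis), and **MIB-1/Ki-67** (staining the
whole active cycle, G1–S–G2–M). All three estimate the proliferating
fraction, yet cohort studies find the two mitosis-window markers strongly
correlated with each other and distinctly less correlated with MIB-1.

For an asynchronously cycling population observed at a single instant, the
fraction of cycling cells caught in mitosis equals mitosis's share of the
cycle,

    N_m / N_c = T_m / T_c = T_m / (T_m + T_i),

so the expected count ratio is **PhH3/MIB-1 = T_m / (T_m + T_i)**. T_m is
comparatively stable across tumors, but interphase T_i is not — aneuploid
tumors run 25–30% longer S phases, and high-grade tumors run longer cycles
overall — so the ratio varies across a cohort and the whole-cycle marker
*decouples* from the mitosis-window markers even when every count is
exact. With a 1-hour mitosis in a 24-hour cycle, 4.17% of MIB-1-positive
cells stain for PhH3; stretch interphase 30% to 29.9 h and it drops to
3.24%, a 22.3% relative decrease.

`prolifsim` makes this mechanism testable end to end, for image-analysis
and quantitative-pathology developers: it simulates grade-stratified tumor
cohorts with explicit phase durations, renders H-DAB / H&E microscope
fields with exact ground truth, counts them with the classical five-step
chain (color deconvolution → minimum filter → robust automatic threshold
selection → watershed → particle count), measures nuclear integrated
optical density (IOD) as a DNA-content proxy, and runs the cohort
statistics (Pearson matrix, MIB-1-on-PhH3 regression, above-line-by-grade
Fisher exact test, grade t tests).

## Worked example

```r
library(prolifsim)

d <- cell_cycle_durations(t_g1 = 11, t_s = 8, t_g2 = 4, t_m = 1)
d
#> Cell-cycle durations (h): G1=11 S=8 G2=4 M=1 | interphase=23 cycle=24
round(100 * phh3_mib1_ratio(d), 2)
#> [1] 4.17

rep <- run_experiment(cohort_config(), seed = 1,
                      rconfig = render_config(width = 400L, height = 300L,
                                              radius_range = c(8, 12)))
rep
#> Synthetic proliferation-marker experiment (n = 49 tumors, seed 1)
#>   regression: MIB-1 = 25.5 x PhH3 + -1 (r = 0.94)
#>   above-line (grade 1-2 vs 3) Fisher p = 0.0003
#>   r(mitoses, PhH3) = 0.99, r(MIB-1, PhH3) = 0.94
#>   PhH3/MIB-1 vs T_m/(T_m+T_i): mean |relative error| = 9.8%
```

Reading the output: the simulated 49-tumor cohort (8/21/20 by grade)
reproduces the characteristic structure — the same-window pair (mitoses,
PhH3) correlates at 0.99 while MIB-1 reaches only 0.94 against either;
grade-3 tumors sit disproportionately **above** the MIB-1-on-PhH3
regression line (Fisher p = 3e-4), i.e. they carry more MIB-1 per unit
PhH3 because their interphase is longer; and each tumor's measured
PhH3/MIB-1 ratio matches the phase-occupancy prediction T_m/(T_m+T_i)
to ~10% (a +5% systematic piece from the 0.95 MIB-1 antibody sensitivity,
the rest Poisson counting noise). `rep$imaging` holds the rendered-field
validation: the five-step chain recounts the synthetic fields to their
ground truth.

## Analysis workflow

The `analysis/` scripts are thin narrative drivers over the package,
writing tables under `results/`:

| script | what it does |
|---|---|
| `01_decoupling_model.R` | worked ratio examples, the decoupling curve CSV, growth-law comparison |
| `02_simulate_cohort.R` | default 49-tumor cohort → measured + ground-truth CSVs, grade summary |
| `03_imaging_validation.R` | renders MIB-1/PhH3/H&E fields, recounts them, measures IOD |
| `04_cohort_stats.R` | correlation matrix, regression, above-line Fisher test, t tests, figures |
| `05_model_comparison.R` | observed vs predicted PhH3/MIB-1; correlation ordering across 50 replicate cohorts |

Run them in order from the repository root, e.g.
`Rscript analysis/02_simulate_cohort.R`.

The methods vignette (`vignettes/marker-decoupling.Rmd`) documents the
models, every tunable default and why, what the synthetic data does and
does not emulate, and the package's numerical choices.

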