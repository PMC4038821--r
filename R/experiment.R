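#' Run the full synthetic experiment
#'
#' Simulates a grade-stratified cohort, computes the Results-style statistics
#' (correlation matrix, MIB-1-on-PhH3 regression, above-line-by-grade Fisher
#' test, grade t-tests), compares measured PhH3/MIB-1 ratios against the
#' phase-occupancy prediction, and — for a small subset of tumors — renders
#' synthetic fields, recounts them with the five-step image chain, and
#' measures nuclear IOD from the rendered H&E, validating the imaging path
#' against its ground truth.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed driving every stage.
#' @param rconfig A [render_config()] for the imaging subset (use a small
#'   field for speed; counts are scaled by field area).
#' @param cconfig A [counting_config()]; its `rats_lambda` should suit the
#'   render noise (see [estimate_rats_lambda()]).
#' @param n_imaged_tumors Number of tumors run through the rendering +
#'   counting + IOD path (0 disables imaging).
#' @param out_dir If non-`NULL`, write cohort CSVs and result JSONs there.
#' @return A list of class `experiment_report`; see the elements
#'   `cohort`, `correlations`, `fit`, `contingency`, `fisher_p`,
#'   `grade_tests`, `summary`, `model_comparison`, `imaging`, `config`,
#'   `seed`.
#' @export
run_experiment <- function(config = cohort_config(), seed = 1L,
                           rconfig = render_config(width = 400L, height = 300L),
                           cconfig = NULL,
                           n_imaged_tumors = 2L,
                           out_dir = NULL) {
  cohort <- simulate_cohort(config, seed = seed)
  if (nrow(cohort) < 3L) stop("experiment error [simulate]: cohort too small", call. = FALSE)

  correlations <- correlation_matrix(cohort)
  fit <- ols_fit(cohort$phh3_per_field, cohort$mib1_per_field)
  cls <- classify_above_line(cohort, fit)
  fisher_p <- fisher_exact_2x2(cls$contingency)

  low <- cohort$grade %in% c(1, 2)
  grade_tests <- lapply(stats::setNames(nm = cohort_variables), function(v) {
    tryCatch(two_sample_t(cohort[[v]][low], cohort[[v]][!low]),
             error = function(e) list(t = NA_real_, df = NA_real_, p = NA_real_))
  })

  model_comparison <- compare_to_model(cohort)
  imaging <- if (n_imaged_tumors > 0) {
    image_subset(cohort, config, rconfig, cconfig, n_imaged_tumors, seed)
  } else NULL

  report <- structure(
    list(cohort = cohort, correlations = correlations, fit = fit,
         above = cls$above, contingency = cls$contingency, fisher_p = fisher_p,
         grade_tests = grade_tests, summary = grade_summary(cohort),
         model_comparison = model_comparison, imaging = imaging,
         config = config, seed = seed),
    class = "experiment_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Measured vs model-predicted PhH3/MIB-1 ratios
#'
#' For each tumor the phase-occupancy model predicts a PhH3/MIB-1 count
#' ratio of `t_m / (t_m + t_i)`; the observed ratio is the measured
#' per-field PhH3 over MIB-1 counts. Tumors with a zero MIB-1 count are
#' flagged (`NA` observed ratio).
#'
#' @param cohort A [simulate_cohort()] table (needs the ground-truth
#'   duration columns).
#' @return A data.frame with `tumor_id`, `predicted`, `observed`,
#'   `relative_error` and, as attribute `"rank_correlation"`, the Spearman
#'   correlation between predicted and observed.
#' @export
compare_to_model <- function(cohort) {
  predicted <- cohort$t_m / (cohort$t_m + cohort$t_i)
  observed <- ifelse(cohort$mib1_per_field > 0,
                     cohort$phh3_per_field / cohort$mib1_per_field, NA_real_)
  out <- data.frame(tumor_id = cohort$tumor_id, predicted = predicted,
                    observed = observed,
                    relative_error = (observed - predicted) / predicted)
  ok <- is.finite(out$observed)
  attr(out, "rank_correlation") <- if (sum(ok) >= 3) {
    stats::cor(predicted[ok], observed[ok], method = "spearman")
  } else NA_real_
  out
}

image_subset <- function(cohort, config, rconfig, cconfig, n_imaged_tumors, seed) {
  vectors <- stain_vectors()
  if (is.null(cconfig)) {
    cconfig <- counting_config(vectors = vectors,
                               rats_lambda = estimate_rats_lambda(rconfig, vectors, seed))
  }
  # re-derive the tumor specs from their per-tumor streams
  pick <- unique(round(seq(1, nrow(cohort), length.out = min(n_imaged_tumors, nrow(cohort)))))
  rows <- lapply(pick, function(k) {
    set.seed(tumor_seed(seed, k))
    spec <- sample_tumor_spec(cohort$grade[k], config, tumor_id = cohort$tumor_id[k])
    set.seed(tumor_seed(seed, k) + 1L)
    fld_mib1 <- simulate_field(spec, config, rconfig, "MIB1", vectors)
    fld_phh3 <- simulate_field(spec, config, rconfig, "PHH3", vectors)
    fld_he <- simulate_field(spec, config, rconfig, "HE", vectors)
    n_iod <- min(config$n_iod_nuclei, nrow(fld_he$nuclei))
    iod <- if (n_iod >= 1) {
      tumor_iod(fld_he$rgb, sample_nuclei_masks(fld_he, n_iod), vectors,
                rconfig$bg_intensity, expected_n = n_iod)
    } else NA_real_
    data.frame(
      tumor_id = cohort$tumor_id[k],
      mib1_truth = ground_truth_counts(fld_mib1),
      mib1_counted = count_field(fld_mib1$rgb, cconfig, rconfig$bg_intensity),
      phh3_truth = ground_truth_counts(fld_phh3),
      phh3_counted = count_field(fld_phh3$rgb, cconfig, rconfig$bg_intensity),
      iod = as.numeric(iod)
    )
  })
  do.call(rbind, rows)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort,
               file.path(out_dir, "cohort_measured.csv"),
               file.path(out_dir, "cohort_truth.csv"))
  jsonlite::write_json(
    list(correlations = report$correlations,
         fit = report$fit[c("slope", "intercept", "pearson_r")],
         contingency = report$contingency,
         fisher_p = report$fisher_p,
         grade_tests = report$grade_tests,
         seed = report$seed),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  utils::write.csv(report$model_comparison,
                   file.path(out_dir, "model_comparison.csv"), row.names = FALSE)
  if (!is.null(report$imaging)) {
    utils::write.csv(report$imaging, file.path(out_dir, "imaging_validation.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Synthetic proliferation-marker experiment (n = %d tumors, seed %d)\n",
              nrow(x$cohort), x$seed))
  cat(sprintf("  regression: MIB-1 = %.1f x PhH3 + %.0f (r = %.2f)\n",
              x$fit$slope, x$fit$intercept, x$fit$pearson_r))
  cat(sprintf("  above-line (grade 1-2 vs 3) Fisher p = %.2g\n", x$fisher_p))
  cat(sprintf("  r(mitoses, PhH3) = %.2f, r(MIB-1, PhH3) = %.2f\n",
              x$correlations["mitoses_per_10hpf", "phh3_per_field"],
              x$correlations["mib1_per_field", "phh3_per_field"]))
  mare <- mean(abs(x$model_comparison$relative_error), na.rm = TRUE)
  cat(sprintf("  PhH3/MIB-1 vs T_m/(T_m+T_i): mean |relative error| = %.1f%%\n",
              100 * mare))
  invisible(x)
}
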