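#' Configuration of a synthetic tumor cohort
#'
#' Defines the grade-stratified parameter distributions from which tumors are
#' drawn, and the observation model tying phase occupancy to per-field counts.
#' Defaults emulate a consecutive invasive breast-carcinoma series: grade
#' split 8/21/20, proliferating fractions rising steeply with grade so that
#' MIB-1 counts per 10x field land near 180/320/900, grade-coupled DNA index
#' (aneuploidy) lengthening S phase, and longer baseline cycles in high-grade
#' tumors.
#'
#' @param n_per_grade Integer vector of length 3: tumors per grade.
#' @param p_cycling_mean Mean proliferating fraction per grade.
#' @param p_cycling_sdlog Log-normal dispersion (sdlog) of `p_cycling` within
#'   grade; counts in such series are strongly right-skewed (sd of the same
#'   order as the mean), which a log-normal with sdlog ~ 0.75 reproduces.
#' @param dna_index_mean,dna_index_sd Per-grade mean/sd of DNA index
#'   (1 = diploid), truncated at 1.
#' @param t_g1_mean Per-grade mean G1 duration (hours); high-grade tumors run
#'   longer cycles.
#' @param t_g1_sdlog Log-normal dispersion of G1 duration across tumors.
#'   Cycle times vary severalfold between tumors (24 h and 72 h are both
#'   realistic); sdlog 0.5 puts the central 95% of G1 durations across a
#'   ~7-fold range, spreading total cycle time roughly 2.5-fold.
#' @param t_s_base Baseline S-phase duration (hours) for a diploid tumor.
#' @param s_phase_ploidy_factor Fractional S lengthening per unit DNA-index
#'   excess: `t_s = t_s_base * (1 + factor * (dna_index - 1))`. Default 0.30
#'   (aneuploid tumors run ~25-30% longer S phases).
#' @param t_g2 G2 duration (hours, fixed).
#' @param t_m_mean,t_m_sd Mitosis duration mean/sd (hours); drawn
#'   independently of ploidy, truncated below at 0.5 h.
#' @param mib1_sensitivity Probability a cycling cell stains MIB-1 positive.
#' @param phh3_window_frac PhH3 staining window as a fraction of `t_m`
#'   (1 = exactly mitosis; values > 1 extend into late G2).
#' @param mitvis_window_frac H&E mitotic-figure visibility window as a
#'   fraction of `t_m` (early prophase and telophase figures are missed).
#' @param detection_prob_mitosis Probability a visible figure is counted.
#' @param nuclei_per_field Expected tumor nuclei per full 10x field.
#' @param n_fields_range Inclusive range of fields imaged per tumor.
#' @param hpf_per_field Area ratio of one 10x camera field to one manually
#'   counted high-power field. The 40x camera crop covers 1/16 of the 10x
#'   sensor field, but manual mitosis counting sweeps the full 40x ocular
#'   field (~0.24 mm^2 with a standard 22 mm eyepiece), about a quarter of
#'   the ~0.6 mm^2 10x camera field — hence the default 4. Set 16 to model
#'   counting on 40x camera crops instead.
#' @param n_hpf High-power fields over which mitoses are summed.
#' @param n_iod_nuclei Nuclei delineated per tumor for IOD.
#' @param iod_scale Integrated optical density per unit relative DNA content
#'   (arbitrary units, sets the scale of the IOD column).
#' @param iod_cv Per-nucleus coefficient of variation of measured IOD
#'   (section thickness, nuclear truncation, stain batch).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_grade = c(8L, 21L, 20L),
                          p_cycling_mean = c(0.065, 0.115, 0.32),
                          p_cycling_sdlog = 0.75,
                          dna_index_mean = c(1.05, 1.30, 1.70),
                          dna_index_sd = c(0.10, 0.25, 0.40),
                          t_g1_mean = c(10, 12, 15),
                          t_g1_sdlog = 0.5,
                          t_s_base = 8,
                          s_phase_ploidy_factor = 0.30,
                          t_g2 = 3.5,
                          t_m_mean = 1.0,
                          t_m_sd = 0.1,
                          mib1_sensitivity = 0.95,
                          phh3_window_frac = 1.0,
                          mitvis_window_frac = 0.8,
                          detection_prob_mitosis = 0.9,
                          nuclei_per_field = 3000,
                          n_fields_range = c(4L, 12L),
                          hpf_per_field = 4,
                          n_hpf = 10L,
                          n_iod_nuclei = 15L,
                          iod_scale = 1250,
                          iod_cv = 0.2) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$n_per_grade) == 3L, all(cfg$n_per_grade >= 0))
  probs <- c(cfg$p_cycling_mean, cfg$mib1_sensitivity, cfg$detection_prob_mitosis)
  if (any(probs < 0 | probs > 1)) {
    stop("invalid parameter: probabilities must lie in [0,1]", call. = FALSE)
  }
  stopifnot(cfg$s_phase_ploidy_factor >= 0, cfg$nuclei_per_field > 0,
            length(cfg$n_fields_range) == 2L,
            cfg$n_fields_range[1] >= 1, cfg$n_fields_range[2] >= cfg$n_fields_range[1])
  class(cfg) <- "cohort_config"
  cfg
}

# Deterministic per-tumor RNG stream: reproducible under cohort re-ordering.
tumor_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(index) %% 104729L
}

#' Draw one tumor's ground-truth parameters
#'
#' Samples proliferating fraction, DNA index and phase durations from the
#' grade-specific distributions of a [cohort_config()]. S phase lengthens
#' with DNA-index excess (`t_s = t_s_base * (1 + factor*(dna_index - 1))`);
#' mitosis duration is drawn independently of ploidy.
#'
#' @param grade Tumor grade, 1, 2 or 3.
#' @param config A [cohort_config()].
#' @param tumor_id Identifier carried into the returned tumor record.
#' @return A list of class `tumor_spec` with fields `tumor_id`, `grade`,
#'   `p_cycling`, `dna_index`, `durations` ([cell_cycle_durations()]),
#'   `nuclei_per_field`, `n_fields`.
#' @export
sample_tumor_spec <- function(grade, config, tumor_id = paste0("T", grade)) {
  if (!grade %in% 1:3) stop("invalid parameter: grade must be 1, 2 or 3", call. = FALSE)
  g <- as.integer(grade)
  mu <- config$p_cycling_mean[g]
  sdl <- config$p_cycling_sdlog
  p <- stats::rlnorm(1, meanlog = log(mu) - sdl^2 / 2, sdlog = sdl)
  p <- min(max(p, 0.002), 0.9)
  dna_index <- max(1, stats::rnorm(1, config$dna_index_mean[g], config$dna_index_sd[g]))
  t_g1 <- stats::rlnorm(1, meanlog = log(config$t_g1_mean[g]) - config$t_g1_sdlog^2 / 2,
                        sdlog = config$t_g1_sdlog)
  t_s <- config$t_s_base * (1 + config$s_phase_ploidy_factor * (dna_index - 1))
  t_m <- max(0.5, stats::rnorm(1, config$t_m_mean, config$t_m_sd))
  n_fields <- if (config$n_fields_range[1] == config$n_fields_range[2]) {
    config$n_fields_range[1]
  } else {
    sample(seq(config$n_fields_range[1], config$n_fields_range[2]), 1)
  }
  structure(
    list(tumor_id = tumor_id, grade = g, p_cycling = p, dna_index = dna_index,
         durations = cell_cycle_durations(t_g1, t_s, config$t_g2, t_m),
         nuclei_per_field = config$nuclei_per_field, n_fields = as.integer(n_fields)),
    class = "tumor_spec"
  )
}

#' Snapshot of cell states at a fixed observation time
#'
#' Draws `n` cells from the asynchronous steady state of one tumor: a cell is
#' cycling with probability `p_cycling` and, if cycling, sits at a uniform
#' position along the cycle, so phase membership is proportional to phase
#' duration. Marker positivity follows the observation model (MIB-1
#' sensitivity; PhH3 window at the end of the cycle; mitotic visibility
#' window centred within M). Relative DNA content is `dna_index` in G0/G1,
#' ramps linearly to `2 * dna_index` across S, and stays doubled through
#' G2/M.
#'
#' @param spec A [sample_tumor_spec()] result.
#' @param config A [cohort_config()].
#' @param n Number of cells to draw.
#' @return A data.frame with columns `phase` (factor G0/G1/S/G2/M),
#'   `mib1_pos`, `phh3_pos`, `mitotically_visible`, `dna_content`.
#' @export
sample_cell_snapshot <- function(spec, config, n = 1L) {
  d <- spec$durations
  cycling <- stats::runif(n) < spec$p_cycling
  pos <- ifelse(cycling, stats::runif(n, 0, d$t_c), NA_real_)
  phase <- rep("G0", n)
  phase[cycling & pos < d$t_g1] <- "G1"
  phase[cycling & pos >= d$t_g1 & pos < d$t_g1 + d$t_s] <- "S"
  phase[cycling & pos >= d$t_g1 + d$t_s & pos < d$t_i] <- "G2"
  phase[cycling & pos >= d$t_i] <- "M"

  phh3_window <- config$phh3_window_frac * d$t_m
  if (phh3_window > d$t_c) stop("invalid parameter: PhH3 window exceeds cycle", call. = FALSE)
  phh3_pos <- cycling & pos >= d$t_c - phh3_window

  mv <- config$mitvis_window_frac * d$t_m
  lo <- d$t_i + (d$t_m - mv) / 2
  visible <- cycling & pos >= lo & pos < lo + mv
  mitotically_visible <- visible & stats::runif(n) < config$detection_prob_mitosis

  mib1_pos <- cycling & stats::runif(n) < config$mib1_sensitivity

  frac_s <- ifelse(phase == "S", (pos - d$t_g1) / d$t_s, 0)
  mult <- ifelse(phase %in% c("G2", "M"), 2, 1 + frac_s)
  dna_content <- spec$dna_index * mult

  data.frame(
    phase = factor(phase, levels = c("G0", "G1", "S", "G2", "M")),
    mib1_pos = mib1_pos, phh3_pos = phh3_pos,
    mitotically_visible = mitotically_visible,
    dna_content = dna_content
  )
}

marker_fractions_for <- function(spec, config) {
  expected_marker_fractions(
    spec$durations, spec$p_cycling,
    mib1_sensitivity = config$mib1_sensitivity,
    phh3_window = config$phh3_window_frac * spec$durations$t_m,
    mitvis_window = config$mitvis_window_frac * spec$durations$t_m
  )
}

#' Simulate per-field marker counts for one tumor
#'
#' Expected counts per 10x field are `nuclei_per_field` times the expected
#' marker fractions; observed counts are Poisson. Mitoses are counted over
#' `n_hpf` high-power fields, each covering `1/hpf_per_field` of a 10x field,
#' and thinned by the manual detection probability.
#'
#' @param spec A [sample_tumor_spec()] result.
#' @param config A [cohort_config()].
#' @return A list with `mib1` and `phh3` (integer vectors, one entry per 10x
#'   field) and `mitoses_per_10hpf` (a single integer).
#' @export
simulate_field_counts <- function(spec, config) {
  f <- marker_fractions_for(spec, config)
  lam_mib1 <- spec$nuclei_per_field * f$f_mib1
  lam_phh3 <- spec$nuclei_per_field * f$f_phh3
  lam_mit_10hpf <- spec$nuclei_per_field * f$f_mitotic *
    config$detection_prob_mitosis * config$n_hpf / config$hpf_per_field
  list(
    mib1 = stats::rpois(spec$n_fields, lam_mib1),
    phh3 = stats::rpois(spec$n_fields, lam_phh3),
    mitoses_per_10hpf = stats::rpois(1L, lam_mit_10hpf)
  )
}

simulate_tumor_iod <- function(spec, config) {
  snap <- sample_cell_snapshot(spec, config, n = config$n_iod_nuclei)
  per_nucleus <- config$iod_scale * snap$dna_content *
    pmax(0, 1 + stats::rnorm(config$n_iod_nuclei, 0, config$iod_cv))
  mean(per_nucleus)
}

#' Simulate a grade-stratified cohort of tumors
#'
#' Draws `n_per_grade` tumors per grade, simulates their per-field marker
#' counts, mitotic counts and nuclear IOD, and returns one row per tumor.
#' Reproducible under a fixed seed; each tumor consumes its own RNG stream
#' keyed by its index, so results do not depend on cohort ordering.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A data.frame (one row per tumor) with measured columns
#'   `mib1_per_field`, `phh3_per_field`, `mitoses_per_10hpf`, `iod` and
#'   ground-truth columns `p_cycling`, `dna_index`, `t_g1`, `t_s`, `t_g2`,
#'   `t_m`, `t_i`, `t_c`, `n_fields`.
#' @examples
#' tab <- simulate_cohort(cohort_config(n_per_grade = c(2, 2, 2)), seed = 1)
#' tab[, c("tumor_id", "grade", "mib1_per_field", "phh3_per_field")]
#' @export
simulate_cohort <- function(config, seed = 1L) {
  grades <- rep(1:3, times = config$n_per_grade)
  n <- length(grades)
  if (n == 0L) {
    return(empty_cohort_table())
  }
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    set.seed(tumor_seed(seed, k))
    spec <- sample_tumor_spec(grades[k], config, tumor_id = sprintf("T%03d", k))
    counts <- simulate_field_counts(spec, config)
    iod <- simulate_tumor_iod(spec, config)
    d <- spec$durations
    rows[[k]] <- data.frame(
      tumor_id = spec$tumor_id, grade = spec$grade,
      mib1_per_field = mean(counts$mib1),
      phh3_per_field = mean(counts$phh3),
      mitoses_per_10hpf = counts$mitoses_per_10hpf,
      iod = iod,
      p_cycling = spec$p_cycling, dna_index = spec$dna_index,
      t_g1 = d$t_g1, t_s = d$t_s, t_g2 = d$t_g2, t_m = d$t_m,
      t_i = d$t_i, t_c = d$t_c, n_fields = spec$n_fields
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_cohort_table <- function() {
  data.frame(
    tumor_id = character(0), grade = integer(0),
    mib1_per_field = numeric(0), phh3_per_field = numeric(0),
    mitoses_per_10hpf = numeric(0), iod = numeric(0),
    p_cycling = numeric(0), dna_index = numeric(0),
    t_g1 = numeric(0), t_s = numeric(0), t_g2 = numeric(0), t_m = numeric(0),
    t_i = numeric(0), t_c = numeric(0), n_fields = integer(0)
  )
}

measured_columns <- c("tumor_id", "grade", "mib1_per_field", "phh3_per_field",
                      "mitoses_per_10hpf", "iod")
truth_columns <- c("tumor_id", "grade", "p_cycling", "dna_index",
                   "t_g1", "t_s", "t_g2", "t_m", "t_i", "t_c", "n_fields")

#' Write a simulated cohort as measured + ground-truth CSVs
#'
#' @param table A [simulate_cohort()] table.
#' @param measured_path,truth_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(table, measured_path, truth_path) {
  utils::write.csv(table[, measured_columns], measured_path, row.names = FALSE)
  utils::write.csv(table[, truth_columns], truth_path, row.names = FALSE)
  invisible(c(measured_path, truth_path))
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param measured_path Measured-counts CSV.
#' @param truth_path Optional ground-truth CSV to merge back in.
#' @return A data.frame.
#' @export
read_cohort <- function(measured_path, truth_path = NULL) {
  tab <- utils::read.csv(measured_path, stringsAsFactors = FALSE)
  if (!is.null(truth_path)) {
    tab <- merge(tab, utils::read.csv(truth_path, stringsAsFactors = FALSE),
                 by = c("tumor_id", "grade"), sort = FALSE)
  }
  tab
}
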