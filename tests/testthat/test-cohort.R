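test_that("tumor specs follow the ploidy -> S-phase coupling rule", {
  # degenerate config: no dispersion, no coupling -> identical durations
  cfg0 <- cohort_config(p_cycling_sdlog = 1e-9, dna_index_sd = c(0, 0, 0),
                        dna_index_mean = c(1, 1, 1), t_g1_mean = c(10, 10, 10),
                        t_g1_sdlog = 1e-9, t_m_sd = 0, s_phase_ploidy_factor = 0)
  set.seed(1)
  specs <- lapply(1:3, sample_tumor_spec, config = cfg0)
  ts <- vapply(specs, function(s) s$durations$t_s, numeric(1))
  tg1 <- vapply(specs, function(s) s$durations$t_g1, numeric(1))
  expect_equal(ts, rep(cfg0$t_s_base, 3))
  expect_equal(tg1, rep(10, 3), tolerance = 1e-6)

  # hand arithmetic: dna_index 2, factor 0.30, base 10 -> t_s = 13
  cfg1 <- cohort_config(dna_index_mean = c(2, 2, 2), dna_index_sd = c(0, 0, 0),
                        t_s_base = 10, s_phase_ploidy_factor = 0.30)
  set.seed(2)
  expect_equal(sample_tumor_spec(1, cfg1)$durations$t_s, 13)

  expect_error(sample_tumor_spec(4, cohort_config()), "invalid parameter")
})

test_that("proliferating fraction rises with grade across Monte-Carlo draws", {
  cfg <- cohort_config()
  set.seed(3)
  p_by_grade <- vapply(1:3, function(g) {
    mean(vapply(1:1000, function(i) sample_tumor_spec(g, cfg)$p_cycling, numeric(1)))
  }, numeric(1))
  expect_true(p_by_grade[3] > p_by_grade[2])
  expect_true(p_by_grade[2] > p_by_grade[1])
  # configured means recovered within Monte-Carlo error
  expect_equal(p_by_grade, cfg$p_cycling_mean, tolerance = 0.1)
})

test_that("cell snapshots respect phase, marker and DNA-content invariants", {
  cfg <- cohort_config()
  set.seed(4)
  spec <- sample_tumor_spec(3, cfg)

  # quiescent tumor: everything G0 and negative
  spec0 <- spec; spec0$p_cycling <- 0
  snap0 <- sample_cell_snapshot(spec0, cfg, n = 500)
  expect_true(all(snap0$phase == "G0"))
  expect_false(any(snap0$mib1_pos | snap0$phh3_pos | snap0$mitotically_visible))
  expect_equal(snap0$dna_content, rep(spec$dna_index, 500))

  snap <- sample_cell_snapshot(spec, cfg, n = 20000)
  # PhH3 positivity confined to G2/M under default windows; here window = t_m
  expect_true(all(snap$phase[snap$phh3_pos] %in% c("G2", "M")))
  expect_false(any(snap$mib1_pos & snap$phase == "G0"))
  expect_true(all(snap$dna_content >= spec$dna_index - 1e-9 &
                    snap$dna_content <= 2 * spec$dna_index + 1e-9))
  # G2 cells carry doubled DNA: dna_index 1.5 -> content 3
  spec15 <- spec; spec15$dna_index <- 1.5
  s15 <- sample_cell_snapshot(spec15, cfg, n = 20000)
  g2 <- s15$phase == "G2"
  expect_true(any(g2))
  expect_equal(unique(s15$dna_content[g2]), 3)
})

test_that("conditional PhH3|MIB-1 fraction converges to the occupancy ratio", {
  cfg <- cohort_config(mib1_sensitivity = 1, phh3_window_frac = 1)
  spec <- list(tumor_id = "T", grade = 3L, p_cycling = 0.5, dna_index = 1,
               durations = cell_cycle_durations(23, 0, 0, 1),
               nuclei_per_field = 3000, n_fields = 8L)
  class(spec) <- "tumor_spec"
  set.seed(5)
  snap <- sample_cell_snapshot(spec, cfg, n = 1e6)
  n_mib1 <- sum(snap$mib1_pos)
  frac <- sum(snap$phh3_pos & snap$mib1_pos) / n_mib1
  expected <- 1 / 24
  se <- sqrt(expected * (1 - expected) / n_mib1)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("field counts are Poisson around the occupancy expectation", {
  cfg <- cohort_config(n_fields_range = c(10000L, 10000L))
  spec <- list(tumor_id = "T", grade = 3L, p_cycling = 0.5, dna_index = 1,
               durations = cell_cycle_durations(11, 8, 4, 1),
               nuclei_per_field = 1000 / (0.5 * cfg$mib1_sensitivity),
               n_fields = 10000L)
  class(spec) <- "tumor_spec"
  set.seed(6)
  counts <- simulate_field_counts(spec, cfg)
  lam <- 1000
  expect_lt(abs(mean(counts$mib1) - lam), 3 * sqrt(lam / 10000))

  # zero marker fraction -> all-zero counts
  spec0 <- spec; spec0$p_cycling <- 0; spec0$n_fields <- 50L
  c0 <- simulate_field_counts(spec0, cfg)
  expect_true(all(c0$mib1 == 0) && all(c0$phh3 == 0) && c0$mitoses_per_10hpf == 0)
})

test_that("mitoses per 10 HPF scale with the configured HPF-to-field area ratio", {
  spec <- list(tumor_id = "T", grade = 3L, p_cycling = 0.4, dna_index = 1,
               durations = cell_cycle_durations(11, 8, 4, 1),
               nuclei_per_field = 3000, n_fields = 4L)
  class(spec) <- "tumor_spec"
  mitotic_per_field <- 3000 * 0.4 * 1 / 24
  set.seed(7)
  for (ratio in c(4, 16)) {  # ocular HPFs vs 40x camera crops
    cfg <- cohort_config(mitvis_window_frac = 1, detection_prob_mitosis = 1,
                         hpf_per_field = ratio, n_hpf = 10L)
    expected_10hpf <- mitotic_per_field * 10 / ratio
    draws <- vapply(1:2000, function(i) simulate_field_counts(spec, cfg)$mitoses_per_10hpf,
                    numeric(1))
    expect_lt(abs(mean(draws) - expected_10hpf),
              3 * sqrt(expected_10hpf / 2000))
  }
})

test_that("cohort simulation is reproducible, grade-ordered, and order-invariant", {
  cfg <- cohort_config(n_per_grade = c(4L, 4L, 4L))
  expect_equal(nrow(simulate_cohort(cohort_config(n_per_grade = c(0L, 0L, 0L)))), 0L)

  t1 <- simulate_cohort(cfg, seed = 10)
  t2 <- simulate_cohort(cfg, seed = 10)
  expect_identical(t1, t2)
  t3 <- simulate_cohort(cfg, seed = 11)
  expect_false(identical(t1, t3))

  big <- simulate_cohort(cohort_config(n_per_grade = c(30L, 30L, 30L)), seed = 12)
  m <- tapply(big$mib1_per_field, big$grade, mean)
  expect_gt(m["3"], m["1"])
})

test_that("cohort CSV round trip preserves the table", {
  tab <- simulate_cohort(cohort_config(n_per_grade = c(2L, 2L, 2L)), seed = 13)
  mp <- tempfile(fileext = ".csv"); tp <- tempfile(fileext = ".csv")
  write_cohort(tab, mp, tp)
  back <- read_cohort(mp, tp)
  expect_equal(back[, names(tab)], tab, tolerance = 1e-12)
})

test_that("grade-coupled aneuploidy decorrelates MIB-1 from the mitosis markers", {
  cfg <- cohort_config(n_per_grade = c(8L, 21L, 20L))
  res <- vapply(1:30, function(r) {
    cm <- correlation_matrix(simulate_cohort(cfg, seed = 400 + r))
    c(mit_phh3 = cm["mitoses_per_10hpf", "phh3_per_field"],
      mib1_phh3 = cm["mib1_per_field", "phh3_per_field"],
      mib1_mit = cm["mib1_per_field", "mitoses_per_10hpf"],
      iod_max = max(cm["iod", c("mitoses_per_10hpf", "mib1_per_field",
                                "phh3_per_field")]))
  }, numeric(4))
  # the same-window pair correlates best; MIB-1 decouples via T_i variation
  expect_gte(mean(res["mit_phh3", ] > res["mib1_phh3", ]), 0.9)
  expect_gte(mean(res["mit_phh3", ] > res["mib1_mit", ]), 0.9)
  # IOD is the weakest correlate of the marker trio
  expect_gte(mean(res["iod_max", ] < res["mib1_phh3", ]), 0.9)
  # MIB-1's correlations with the two mitosis readouts are near-tied: both
  # are attenuated by cycle-time spread, mitoses only by extra count noise
  expect_lt(mean(abs(res["mib1_mit", ] - res["mib1_phh3", ])), 0.05)
})
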