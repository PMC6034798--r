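test_that("medium calibration inverts the forward model", {
  spec <- pulse_spec()
  # c = L / t arithmetic at band centre
  med <- calibrate_medium(c(`6`= 100), c(`4` = 0.2, `10` = 0.5), spec,
                          path_length_m = 0.154)
  expect_equal(phase_velocity(med, mean(range(spec$frequencies_hz))),
               1540, tolerance = 1e-6)

  # attenuation targets at the published scale reproduce exactly
  med2 <- calibrate_medium(
    c(`2` = 97.71167, `6` = 97.65715, `10` = 97.51462),
    c(`4` = 0.1558638, `10` = 0.4921344),
    spec, path_length_m = 0.15
  )
  f <- spec$frequencies_hz
  expect_equal(1 - component_gains(med2, f[c(4, 10)]),
               c(0.1558638, 0.4921344), tolerance = 1e-9)
  expect_gt(med2$attenuation_exponent, 0)

  # infeasible targets are named errors
  expect_error(
    calibrate_medium(c(`6` = 100), c(`4` = 0.5, `10` = 0.2), spec, 0.15),
    "calibration error"
  )
  expect_error(
    calibrate_medium(c(`6` = 100), c(`4` = 0.3, `10` = 0.3), spec, 0.15,
                     gamma_min = 0.1),
    "calibration error"
  )
  expect_error(
    calibrate_medium(c(`6` = -1), c(`4` = 0.2, `10` = 0.5), spec, 0.15),
    "positive"
  )
})

test_that("cohorts are reproducible and sized like the study", {
  cfg <- cohort_config(seed = 31)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$subjects, coh2$subjects)
  expect_equal(nrow(coh1$subjects), 97)
  expect_equal(sum(coh1$subjects$group == "hypertension"), 75)
  expect_equal(sum(coh1$subjects$group == "no_hypertension"), 22)
  # head circumference at the published 57 +/- 2 cm
  expect_equal(mean(coh1$subjects$head_circumference_cm), 57, tolerance = 0.03)
})

test_that("subjects' latent values equal their medium's forward features", {
  cfg <- cohort_config(seed = 5)
  coh <- generate_cohort(cfg)
  f <- cfg$spec$frequencies_hz
  for (i in c(1, 50, 97)) {
    med <- coh$media[[coh$subjects$subject_id[i]]]
    toa <- component_delays(med, f[c(2, 6, 10)]) * 1e6
    expect_equal(unlist(coh$subjects[i, paste0("latent_toa_", c(2, 6, 10))],
                        use.names = FALSE), toa, tolerance = 1e-9)
    att <- 1 - component_gains(med, f[c(4, 9, 10)])
    expect_equal(unlist(coh$subjects[i, paste0("latent_att_", c(4, 9, 10))],
                        use.names = FALSE), att, tolerance = 1e-9)
  }
})

test_that("covariate sampling matches the configured rates", {
  cfg <- cohort_config(n_hypertension = 1200, n_no_hypertension = 2,
                       seed = 17)
  coh <- generate_cohort(cfg)
  ht <- coh$subjects[coh$subjects$group == "hypertension", ]
  for (v in c("cad", "diabetes", "smoking")) {
    target <- cfg$covariates$rate_ht[cfg$covariates$covariate == v]
    se <- sqrt(target * (1 - target) / 1200)
    expect_lt(abs(mean(ht[[v]]) - target), 4 * se)
  }
  expect_lt(abs(mean(ht$age) - 66), 4 * 6 / sqrt(1200))
})

test_that("a null configuration removes the group separation", {
  cfg0 <- cohort_config(effect_scale = 0)
  st <- acgtools:::scaled_targets(cfg0)
  expect_equal(st$mean_ht, st$mean_no_ht)
  # and unit scale restores the configured group means
  cfg1 <- cohort_config(effect_scale = 1)
  expect_equal(acgtools:::scaled_targets(cfg1)$mean_ht,
               cfg1$feature_targets$mean_ht)
})

test_that("small simulated cohorts pass quality and carry 3 records each", {
  cfg <- quick_cohort_config(n_hypertension = 3, n_no_hypertension = 2,
                             seed = 23)
  coh <- generate_cohort(cfg, simulate_records = TRUE)
  expect_length(coh$records, 5)
  qualities <- unlist(purrr::map(coh$records, function(exam) {
    purrr::map_dbl(exam$records, "quality")
  }))
  expect_length(qualities, 15)
  expect_true(all(qualities > 0.70))
})

test_that("waveform extraction agrees with the latent feature values", {
  cfg <- quick_cohort_config(
    n_hypertension = 2, n_no_hypertension = 2, seed = 29,
    snr_db = NULL, toa_noise_us = 0, att_noise = 0, energy_rel_noise = 0
  )
  coh <- generate_cohort(cfg, simulate_records = TRUE)
  latent <- cohort_features(coh, mode = "latent", seed = 1)
  signal <- cohort_features(coh, mode = "signal")
  toa_cols <- sprintf("ToA_f%02d", 1:10)
  att_cols <- sprintf("ATT_f%02d", 1:10)
  expect_equal(as.matrix(signal[toa_cols]), as.matrix(latent[toa_cols]),
               tolerance = 1e-6)
  expect_equal(as.matrix(signal[att_cols]), as.matrix(latent[att_cols]),
               tolerance = 1e-6)
  # FFT band energies agree up to spectral leakage
  fft_cols <- sprintf("FFT_e%02d", 1:10)
  expect_equal(as.matrix(signal[fft_cols]), as.matrix(latent[fft_cols]),
               tolerance = 0.02)
})

test_that("the exam-aggregated feature means track the configured targets", {
  # pooled over four cohorts so the check sits at the 2-SE level of the
  # pooled sampling distribution
  means <- sapply(1:4, function(s) {
    coh <- generate_cohort(cohort_config(seed = 40 + s))
    feats <- cohort_features(coh, seed = 140 + s)
    mean(feats$ToA_f02[feats$group == "hypertension"])
  })
  cfg <- cohort_config()
  target <- cfg$feature_targets$mean_ht[cfg$feature_targets$component == 2 &
                                          cfg$feature_targets$feature == "toa"]
  se_pooled <- cfg$feature_targets$sd_ht[1] / sqrt(4 * 75)
  expect_lt(abs(mean(means) - target), 2 * se_pooled)
})

test_that("baseline tables reproduce the published counts and p-values", {
  # subjects hard-coded to the published CAD counts: 8/22 vs 41/75
  subjects <- tibble::tibble(
    group = rep(c("no_hypertension", "hypertension"), c(22, 75)),
    cad = c(rep(1, 8), rep(0, 14), rep(1, 41), rep(0, 34)),
    empty = 0
  )
  bt <- baseline_table(subjects)
  cad <- bt[bt$variable == "cad", ]
  expect_equal(cad$summary_no_ht, "8 (36%)")
  expect_equal(cad$summary_ht, "41 (55%)")
  expect_equal(round(cad$p_value, 2), 0.15)
  # counts sum to group sizes
  expect_equal(cad$count_no_ht + (22 - cad$count_no_ht), 22)
  # a covariate absent from both groups is uninformative
  subjects$cad <- NULL
  subjects$smoking <- 0
  bt2 <- baseline_table(subjects)
  expect_equal(bt2$p_value[bt2$variable == "smoking"], 1)
})

test_that("the configured separation scales linearly with effect size", {
  es <- effect_scale_for_separation(target_distance = 3)
  expect_equal(es$effect_scale * es$distance_at_unit_scale, 3)
  es2 <- effect_scale_for_separation(target_distance = 6)
  expect_equal(es2$effect_scale, 2 * es$effect_scale)
})
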