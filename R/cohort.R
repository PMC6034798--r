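#' Default covariate prevalence table for synthetic cohorts
#'
#' Per-group prevalences of the binary baseline covariates of an
#' AF case-control cohort of 22 non-hypertensive and 75 hypertensive
#' subjects (female sex, coronary artery disease, diabetes, vascular and
#' thyroid disease, asthma, smoking, family history of stroke and of
#' heart disease).
#'
#' @return a tibble with columns `covariate`, `rate_no_ht`, `rate_ht`.
#' @export
covariate_defaults <- function() {
  tibble::tribble(
    ~covariate,      ~rate_no_ht, ~rate_ht,
    "female",        8 / 22,      33 / 75,
    "cad",           8 / 22,      41 / 75,
    "diabetes",      3 / 22,      22 / 75,
    "vascular",      1 / 22,      7 / 75,
    "thyroid",       3 / 22,      8 / 75,
    "asthma",        1 / 22,      3 / 75,
    "smoking",       4 / 22,      8 / 75,
    "fam_stroke",    5 / 22,      21 / 75,
    "fam_heart",     8 / 22,      12 / 75
  )
}

#' Default per-group feature targets (time of flight and attenuation)
#'
#' Group means and standard deviations of the per-frequency time of
#' flight (microseconds; components 2, 6, 10) and fractional attenuation
#' (components 4, 9, 10) that the synthetic cohort generator calibrates
#' its media to, on the scale reported for hypertensive vs
#' non-hypertensive AF cohorts.
#'
#' @return a tibble with columns `feature`, `component`, `mean_ht`,
#'   `sd_ht`, `mean_no_ht`, `sd_no_ht`.
#' @export
feature_target_defaults <- function() {
  tibble::tribble(
    ~feature, ~component, ~mean_ht,   ~sd_ht,     ~mean_no_ht, ~sd_no_ht,
    "toa",    2L,         97.71167,   3.740836,   98.8017,     3.876631,
    "toa",    6L,         97.65715,   3.743918,   98.76313,    3.926999,
    "toa",    10L,        97.51462,   3.692365,   98.60944,    3.929389,
    "att",    4L,         0.1558638,  0.1211638,  0.1406993,   0.1293839,
    "att",    9L,         0.5305551,  0.1638107,  0.5686885,   0.1699262,
    "att",    10L,        0.4921344,  0.1867929,  0.5723731,   0.1794155
  )
}

#' Configuration of a synthetic ACG cohort
#'
#' Describes the study conditions emulated by [generate_cohort()]: group
#' sizes (75 hypertensive, 22 non-hypertensive), baseline covariate
#' rates, age and head-circumference distributions, and the per-group
#' time-of-flight/attenuation targets the tissue media are calibrated to.
#'
#' `effect_scale` multiplies the between-group difference of the feature
#' targets about their pooled (size-weighted) mean: 0 gives a null cohort
#' with identical group distributions, 1 the published separations.
#'
#' @param n_hypertension,n_no_hypertension group sizes (>= 2 each).
#' @param covariates covariate prevalence tibble, see
#'   [covariate_defaults()].
#' @param feature_targets feature target tibble, see
#'   [feature_target_defaults()].
#' @param age_no_ht,age_ht `c(mean, sd)` of age in years per group.
#' @param head_circumference_cm `c(mean, sd)` of head circumference.
#' @param effect_scale multiplier on the between-group separation.
#' @param ar_corr correlation between per-frequency attenuation values,
#'   decaying as `ar_corr^|i - j|` with component distance (adjacent
#'   components share most of the tissue path).
#' @param head_size_share share of the common time-of-flight variance
#'   attributed to head-size (path length) variation; the rest is bulk
#'   tissue-velocity variation.
#' @param toa_dispersion_share share of a subject's time-of-flight
#'   variance that is differential across frequency (true per-subject
#'   dispersion) rather than common-mode. Must be small: a subject's
#'   transit times at different frequencies move almost together (head
#'   size and bulk velocity), and the default 5e-4 puts per-subject
#'   dispersion slopes at the ~1 m/s/MHz scale a phase-based multitone
#'   instrument can actually resolve.
#' @param spec [pulse_spec()] used for the cohort's records.
#' @param snr_db receiver SNR for simulated records.
#' @param toa_noise_us,att_noise,energy_rel_noise per-record measurement
#'   noise of the extracted features (defaults reflect the ~5.6 ns device
#'   timing precision and sub-percent amplitude stability).
#' @param record_duration_s,window_s record length and analysis window.
#' @param seed integer seed; the whole cohort is reproducible given it.
#' @return a list of class `acg_cohort_config`.
#' @export
cohort_config <- function(n_hypertension = 75,
                          n_no_hypertension = 22,
                          covariates = covariate_defaults(),
                          feature_targets = feature_target_defaults(),
                          age_no_ht = c(64, 8),
                          age_ht = c(66, 6),
                          head_circumference_cm = c(57, 2),
                          effect_scale = 1,
                          ar_corr = 0.8,
                          head_size_share = 0.5,
                          toa_dispersion_share = 5e-4,
                          spec = pulse_spec(),
                          snr_db = 30,
                          toa_noise_us = 0.0056,
                          att_noise = 0.005,
                          energy_rel_noise = 0.01,
                          record_duration_s = 30,
                          window_s = 10,
                          seed = NULL) {
  stopifnot(n_hypertension >= 2, n_no_hypertension >= 2)
  if (any(covariates$rate_no_ht < 0 | covariates$rate_no_ht > 1) ||
      any(covariates$rate_ht < 0 | covariates$rate_ht > 1)) {
    stop("covariate rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(feature_targets$sd_ht <= 0) || any(feature_targets$sd_no_ht <= 0)) {
    stop("feature target SDs must be positive", call. = FALSE)
  }
  structure(
    list(
      n_hypertension = n_hypertension,
      n_no_hypertension = n_no_hypertension,
      covariates = covariates,
      feature_targets = feature_targets,
      age_no_ht = age_no_ht, age_ht = age_ht,
      head_circumference_cm = head_circumference_cm,
      effect_scale = effect_scale,
      ar_corr = ar_corr,
      head_size_share = head_size_share,
      toa_dispersion_share = toa_dispersion_share,
      spec = spec,
      snr_db = snr_db,
      toa_noise_us = toa_noise_us,
      att_noise = att_noise,
      energy_rel_noise = energy_rel_noise,
      record_duration_s = record_duration_s,
      window_s = window_s,
      seed = seed
    ),
    class = "acg_cohort_config"
  )
}

# group means after applying effect_scale about the size-weighted pooled mean
scaled_targets <- function(config) {
  ft <- config$feature_targets
  w_ht <- config$n_hypertension /
    (config$n_hypertension + config$n_no_hypertension)
  pooled <- w_ht * ft$mean_ht + (1 - w_ht) * ft$mean_no_ht
  ft$mean_ht <- pooled + config$effect_scale * (ft$mean_ht - pooled)
  ft$mean_no_ht <- pooled + config$effect_scale * (ft$mean_no_ht - pooled)
  ft
}

#' Calibrate a propagation medium to feature targets
#'
#' Inverts the forward model so that noiseless simulation reproduces the
#' requested per-component time of flight and attenuation. Velocities
#' come from `c(f_j) = L / t_j` at each time-of-flight target (a single
#' target fixes a dispersionless medium; two or more fit the linear
#' dispersion law by least squares). The attenuation power law is solved
#' exactly from the two extreme attenuation targets:
#' `gamma = log(aL_hi / aL_lo) / log(f_hi / f_lo)` with
#' `aL_j = -log(1 - ATT_j)`, then `alpha0 = aL_lo / (L (f_lo/1MHz)^gamma)`.
#'
#' @param toa_targets_us named numeric of time-of-flight targets in
#'   microseconds, names = component indices (e.g. `c("2" = 97.7, ...)`).
#' @param att_targets named numeric of fractional attenuation targets in
#'   (0, 1), names = component indices; at least two required, the lowest
#'   and highest component are used.
#' @param spec the [pulse_spec()] defining the component grid.
#' @param path_length_m the acoustic path length L.
#' @param snr_db optional noise level stored on the medium.
#' @param gamma_min smallest admissible attenuation exponent (default 0);
#'   targets implying a smaller exponent raise a calibration error.
#' @return an [medium_model()].
#' @export
calibrate_medium <- function(toa_targets_us, att_targets, spec,
                             path_length_m, snr_db = NULL, gamma_min = 0) {
  stopifnot(inherits(spec, "acg_pulse_spec"))
  f <- spec$frequencies_hz
  f_ref <- mean(range(f))
  if (any(toa_targets_us <= 0)) {
    stop("calibration error: time-of-flight targets must be positive",
         call. = FALSE)
  }
  comp_t <- as.integer(names(toa_targets_us))
  if (length(comp_t) == 0 || any(is.na(comp_t))) {
    stop("`toa_targets_us` must be named by component index", call. = FALSE)
  }
  f_t <- f[comp_t]
  v <- path_length_m / (toa_targets_us * 1e-6)
  if (length(v) == 1) {
    c0 <- unname(v)
    slope <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, (f_t - f_ref) / 1e6), v)
    c0 <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  }
  if (length(att_targets) < 2) {
    stop("calibration error: at least two attenuation targets required",
         call. = FALSE)
  }
  comp_a <- as.integer(names(att_targets))
  if (any(is.na(comp_a))) {
    stop("`att_targets` must be named by component index", call. = FALSE)
  }
  if (any(att_targets <= 0 | att_targets >= 1)) {
    stop("calibration error: attenuation targets must lie in (0, 1)",
         call. = FALSE)
  }
  lo <- which.min(comp_a)
  hi <- which.max(comp_a)
  f_lo <- f[comp_a[lo]]
  f_hi <- f[comp_a[hi]]
  al_lo <- -log(1 - att_targets[lo])
  al_hi <- -log(1 - att_targets[hi])
  if (al_hi < al_lo) {
    stop("calibration error: attenuation decreasing in frequency is ",
         "incompatible with a non-negative power-law exponent",
         call. = FALSE)
  }
  gamma <- if (al_hi == al_lo) 0 else
    log(al_hi / al_lo) / log(f_hi / f_lo)
  if (gamma < gamma_min) {
    stop("calibration error: targets imply attenuation exponent ",
         sprintf("%.4f", gamma), " below the admissible minimum ",
         gamma_min, call. = FALSE)
  }
  alpha0 <- unname(al_lo / (path_length_m * (f_lo / 1e6)^gamma))
  medium_model(
    path_length_m = path_length_m,
    c0_mps = c0,
    dispersion_slope_mps_per_mhz = slope,
    alpha0_np_per_m = alpha0,
    attenuation_exponent = gamma,
    snr_db = snr_db,
    f_ref_hz = f_ref
  )
}

# AR(1)-distance correlation matrix over component indices
component_corr <- function(components, rho) {
  outer(components, components, function(i, j) rho^abs(i - j))
}

#' Draw one synthetic subject
#'
#' Samples covariates (Bernoulli at the group rate), age and head
#' circumference (normal, rounded/continuous respectively), then latent
#' per-component time-of-flight and attenuation values from the group's
#' multivariate-normal targets, and calibrates the subject's propagation
#' medium to them. The path length is the head circumference over pi
#' scaled by 0.85 (temporal-window chord). A `head_size_share` of the
#' time-of-flight variance is driven by the head-size draw, the rest by
#' independent tissue-velocity variation. Attenuation draws infeasible
#' for a non-negative power law are redrawn (up to 100 times) and finally
#' clamped.
#'
#' Uses the R session RNG; seed the caller for reproducibility.
#'
#' @param group `"hypertension"` or `"no_hypertension"`.
#' @param config an [cohort_config()].
#' @param subject_id identifier stored on the subject row.
#' @return a list with `row` (one-row tibble) and `medium`.
#' @export
sample_subject <- function(group = c("hypertension", "no_hypertension"),
                           config = cohort_config(), subject_id = "S001") {
  group <- match.arg(group)
  ht <- group == "hypertension"
  cov <- config$covariates
  rates <- if (ht) cov$rate_ht else cov$rate_no_ht
  flags <- stats::rbinom(nrow(cov), 1, rates)
  names(flags) <- cov$covariate
  age_par <- if (ht) config$age_ht else config$age_no_ht
  age <- round(stats::rnorm(1, age_par[1], age_par[2]))
  hc <- stats::rnorm(1, config$head_circumference_cm[1],
                     config$head_circumference_cm[2])
  z_head <- (hc - config$head_circumference_cm[1]) /
    config$head_circumference_cm[2]
  path_length_m <- hc / pi * 0.85 / 100

  ft <- scaled_targets(config)
  mu <- if (ht) ft$mean_ht else ft$mean_no_ht
  sd <- if (ht) ft$sd_ht else ft$sd_no_ht
  is_toa <- ft$feature == "toa"

  # time of flight: a common-mode part (head size + bulk velocity, split
  # by head_size_share) plus a small independent differential-dispersion
  # part per component
  h <- config$head_size_share
  d <- config$toa_dispersion_share
  n_toa <- sum(is_toa)
  z_vel <- stats::rnorm(1)
  u <- stats::rnorm(n_toa)
  common <- sqrt(h * (1 - d)) * z_head + sqrt((1 - h) * (1 - d)) * z_vel
  toa <- mu[is_toa] + sd[is_toa] * (common + sqrt(d) * u)
  names(toa) <- as.character(ft$component[is_toa])

  # attenuation: correlated draw, rejected until power-law feasible
  r_att <- component_corr(ft$component[!is_toa], config$ar_corr)
  comp_att <- ft$component[!is_toa]
  lo <- which.min(comp_att)
  hi <- which.max(comp_att)
  att <- NULL
  for (try in seq_len(100)) {
    cand <- mu[!is_toa] +
      sd[!is_toa] * drop(MASS::mvrnorm(1, rep(0, sum(!is_toa)), r_att))
    if (cand[lo] > 0 && cand[hi] < 1 && cand[lo] < cand[hi]) {
      att <- cand
      break
    }
  }
  if (is.null(att)) {
    att <- pmax(0.01, pmin(0.98, mu[!is_toa]))
    if (att[lo] >= att[hi]) att[lo] <- att[hi] * 0.5
  }
  names(att) <- as.character(comp_att)

  medium <- calibrate_medium(
    toa_targets_us = toa,
    att_targets = att[c(lo, hi)],
    spec = config$spec,
    path_length_m = path_length_m,
    snr_db = config$snr_db
  )
  # store the medium-implied values as the subject's latent truth so the
  # noiseless extraction round-trip is exact: the three ToA draws are
  # projected onto the linear dispersion law, ATT onto the power law
  f_cal_t <- config$spec$frequencies_hz[as.integer(names(toa))]
  toa[] <- component_delays(medium, f_cal_t) * 1e6
  f_cal_a <- config$spec$frequencies_hz[as.integer(names(att))]
  att[] <- 1 - component_gains(medium, f_cal_a)
  row <- tibble::tibble(
    subject_id = subject_id,
    group = group,
    !!!as.list(flags),
    age = age,
    head_circumference_cm = hc,
    path_length_m = path_length_m,
    c0_mps = medium$c0_mps,
    dispersion_slope_mps_per_mhz = medium$dispersion_slope_mps_per_mhz,
    alpha0_np_per_m = medium$alpha0_np_per_m,
    attenuation_exponent = medium$attenuation_exponent,
    !!!stats::setNames(as.list(toa), paste0("latent_toa_", names(toa))),
    !!!stats::setNames(as.list(att), paste0("latent_att_", names(att)))
  )
  list(row = row, medium = medium)
}

#' Generate a synthetic ACG cohort
#'
#' Draws all subjects of both groups (see [sample_subject()]) and,
#' optionally, simulates their three raw records each through the
#' calibrated media. Record simulation retries the noise draw up to 10
#' times per record until the quality criterion (> 0.70) passes; the
#' quality reference gains come from each subject's own calibrated
#' medium, emulating the device's transmit-amplitude selection.
#'
#' @param config an [cohort_config()]; its `seed` makes the cohort fully
#'   reproducible.
#' @param simulate_records simulate raw waveforms (slow for long records;
#'   the default keeps the cohort at the medium/feature level).
#' @return an object of class `acg_cohort`: list with `subjects` (tibble,
#'   one row per subject), `media` (named list), `records` (named list of
#'   3-record lists, or NULL), `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            simulate_records = FALSE) {
  run <- function() {
    groups <- c(rep("hypertension", config$n_hypertension),
                rep("no_hypertension", config$n_no_hypertension))
    ids <- sprintf("S%03d", seq_along(groups))
    drawn <- purrr::map2(groups, ids,
                         ~ sample_subject(.x, config, subject_id = .y))
    subjects <- purrr::list_rbind(purrr::map(drawn, "row"))
    media <- stats::setNames(purrr::map(drawn, "medium"), ids)
    records <- NULL
    if (simulate_records) {
      records <- purrr::map(ids, function(id) {
        simulate_subject_records(media[[id]], config)
      })
      names(records) <- ids
    }
    structure(
      list(subjects = subjects, media = media, records = records,
           config = config),
      class = "acg_cohort"
    )
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

simulate_subject_records <- function(medium, config, n_records = 3,
                                     max_retries = 10) {
  spec <- config$spec
  spec$amplitudes <- select_transmit_amplitudes(spec, medium)
  tx <- synthesize_pulse(spec, config$record_duration_s)
  f <- spec$frequencies_hz
  ref_gains <- component_gains(medium, c(f[1], f[length(f)]))
  recs <- purrr::map(seq_len(n_records), function(i) {
    for (try in seq_len(max_retries)) {
      rx <- propagate(tx, spec, medium)
      q <- quality_score(rx, spec, tx, reference_gains = ref_gains)
      if (q > 0.70) {
        rx$quality <- q
        return(rx)
      }
    }
    stop("simulation error: record quality stayed below 0.70 after ",
         max_retries, " retries", call. = FALSE)
  })
  list(spec = spec, transmitted = tx, records = recs)
}

#' @export
print.acg_cohort <- function(x, ...) {
  cat(sprintf(
    "<acg_cohort> %d subjects (%d hypertension / %d no hypertension)%s\n",
    nrow(x$subjects), sum(x$subjects$group == "hypertension"),
    sum(x$subjects$group == "no_hypertension"),
    if (is.null(x$records)) "" else
      sprintf(", %d simulated records", 3L * nrow(x$subjects))
  ))
  invisible(x)
}

#' Exam-aggregated feature table of a cohort
#'
#' Returns the classifier-ready table: one row per subject with
#' per-component time of flight (`ToA_f01..`), fractional attenuation
#' (`ATT_f01..`), FFT band energies (`FFT_e01..`) and the spectral
#' centroid.
#'
#' Two modes: `"latent"` (default) evaluates each subject's calibrated
#' medium analytically — exactly what noiseless extraction recovers
#' (verified by the pipeline round-trip tests) — and adds per-record
#' measurement noise at the configured device precisions before taking
#' the three-record median. `"signal"` runs the full waveform pipeline
#' ([extract_exam_features()]) on simulated records and requires
#' `generate_cohort(..., simulate_records = TRUE)`.
#'
#' @param cohort an `acg_cohort`.
#' @param mode `"latent"` or `"signal"`.
#' @param seed optional seed for the measurement-noise draws.
#' @return a tibble, one row per subject, `subject_id` and `group` first.
#' @export
cohort_features <- function(cohort, mode = c("latent", "signal"),
                            seed = NULL) {
  mode <- match.arg(mode)
  run <- function() {
    if (mode == "latent") latent_cohort_features(cohort)
    else signal_cohort_features(cohort)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

latent_cohort_features <- function(cohort) {
  config <- cohort$config
  spec <- config$spec
  f <- spec$frequencies_hz
  nk <- length(f)
  nm <- feature_names(nk)
  rows <- purrr::imap(cohort$media, function(medium, id) {
    toa_true <- component_delays(medium, f) * 1e6
    gains <- component_gains(medium, f)
    att_true <- 1 - gains
    amps <- select_transmit_amplitudes(spec, medium)
    energy_true <- (amps * gains)^2 / 2
    per_rec <- purrr::map(1:3, function(r) {
      toa <- toa_true + stats::rnorm(nk, sd = config$toa_noise_us)
      att <- pmax(0, pmin(1, att_true +
                            stats::rnorm(nk, sd = config$att_noise)))
      en <- energy_true * (1 + stats::rnorm(nk, sd = config$energy_rel_noise))
      centroid <- sum(f * en) / sum(en)
      c(stats::setNames(toa, nm$toa),
        stats::setNames(att, nm$att),
        stats::setNames(en, nm$fft),
        FFT_centroid = centroid)
    })
    med <- apply(do.call(rbind, per_rec), 2, stats::median)
    tibble::as_tibble_row(c(list(subject_id = id), as.list(med)))
  })
  features <- purrr::list_rbind(rows)
  dplyr::left_join(
    dplyr::select(cohort$subjects, "subject_id", "group"),
    features, by = "subject_id"
  )
}

signal_cohort_features <- function(cohort) {
  if (is.null(cohort$records)) {
    stop("cohort has no simulated records; run generate_cohort(",
         "simulate_records = TRUE)", call. = FALSE)
  }
  config <- cohort$config
  rows <- purrr::imap(cohort$records, function(exam, id) {
    fv <- extract_exam_features(
      exam$records, exam$spec, transmitted = exam$transmitted,
      window_s = config$window_s
    )
    dplyr::bind_cols(tibble::tibble(subject_id = id), fv)
  })
  features <- purrr::list_rbind(rows)
  dplyr::left_join(
    dplyr::select(cohort$subjects, "subject_id", "group"),
    features, by = "subject_id"
  )
}

#' Baseline characteristics table of a cohort
#'
#' Per-covariate counts and within-group percentages with two-sided
#' Fisher exact p-values, plus mean (SD) and Kruskal-Wallis p for the
#' quantitative baseline variables (age, head circumference) — the usual
#' case-control baseline-characteristics layout.
#'
#' @param cohort an `acg_cohort` or its `subjects` tibble.
#' @return a tibble with one row per variable: counts/means per group,
#'   percentages/SDs, formatted summaries, `test`, `p_value`.
#' @export
baseline_table <- function(cohort) {
  subjects <- if (inherits(cohort, "acg_cohort")) cohort$subjects else cohort
  ht <- subjects$group == "hypertension"
  n_ht <- sum(ht)
  n_no <- sum(!ht)
  binary_vars <- intersect(covariate_defaults()$covariate, names(subjects))
  cat_rows <- purrr::map(binary_vars, function(v) {
    x <- subjects[[v]]
    a <- sum(x[!ht]); b <- n_no - a
    c_ <- sum(x[ht]); d <- n_ht - c_
    p <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    tibble::tibble(
      variable = v, test = "fisher",
      count_no_ht = a, pct_no_ht = round(100 * a / n_no),
      count_ht = c_, pct_ht = round(100 * c_ / n_ht),
      summary_no_ht = sprintf("%d (%d%%)", a, round(100 * a / n_no)),
      summary_ht = sprintf("%d (%d%%)", c_, round(100 * c_ / n_ht)),
      p_value = p
    )
  }) |> purrr::list_rbind()
  quant_vars <- intersect(c("age", "head_circumference_cm"), names(subjects))
  quant_rows <- purrr::map(quant_vars, function(v) {
    x <- subjects[[v]]
    kw <- kruskal_wallis(split(x, ht))
    tibble::tibble(
      variable = v, test = "kruskal-wallis",
      count_no_ht = NA_real_, pct_no_ht = NA_real_,
      count_ht = NA_real_, pct_ht = NA_real_,
      summary_no_ht = sprintf("%.0f (± %.0f)", mean(x[!ht]),
                              stats::sd(x[!ht])),
      summary_ht = sprintf("%.0f (± %.0f)", mean(x[ht]),
                           stats::sd(x[ht])),
      p_value = kw$p_value
    )
  }) |> purrr::list_rbind()
  dplyr::bind_rows(quant_rows, cat_rows)
}

#' Effect scale needed for a target group separation
#'
#' Computes the Mahalanobis distance between the configured group mean
#' vectors of the latent features under the generator's latent
#' covariance, and returns the `effect_scale` that makes it equal
#' `target_distance` (the distance is linear in `effect_scale`).
#'
#' @param config an [cohort_config()].
#' @param target_distance desired Mahalanobis separation (default 3).
#' @return a list with `effect_scale`, `distance_at_unit_scale`.
#' @export
effect_scale_for_separation <- function(config = cohort_config(),
                                        target_distance = 3) {
  ft <- config$feature_targets
  d <- ft$mean_ht - ft$mean_no_ht
  sd_pool <- sqrt((ft$sd_ht^2 + ft$sd_no_ht^2) / 2)
  is_toa <- ft$feature == "toa"
  sigma <- matrix(0, nrow(ft), nrow(ft))
  # ToA block: common-mode correlation 1 - disp, independent differential
  disp <- config$toa_dispersion_share
  n_toa <- sum(is_toa)
  sigma[is_toa, is_toa] <- (1 - disp) + diag(disp, n_toa)
  sigma[!is_toa, !is_toa] <- component_corr(ft$component[!is_toa],
                                            config$ar_corr)
  sigma <- diag(sd_pool) %*% sigma %*% diag(sd_pool)
  d1 <- sqrt(drop(t(d) %*% solve(sigma, d)))
  list(effect_scale = target_distance / d1, distance_at_unit_scale = d1)
}
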