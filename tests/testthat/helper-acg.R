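# Small signal sizes for tests: same model and estimators as the 30 s /
# 25 MHz study records, millisecond records at 12.5 MHz keep the suite fast.
quick_spec <- function(n_components = 10, sampling_rate_hz = 12.5e6,
                       record_duration_s = 2e-3, ...) {
  pulse_spec(n_components = n_components,
             sampling_rate_hz = sampling_rate_hz,
             record_duration_s = record_duration_s, ...)
}

# head-scale dispersive, attenuating medium
quick_medium <- function(snr_db = NULL, slope = 5, alpha0 = 1.2,
                         gamma = 1.5) {
  medium_model(path_length_m = 0.15, c0_mps = 1540,
               dispersion_slope_mps_per_mhz = slope,
               alpha0_np_per_m = alpha0, attenuation_exponent = gamma,
               snr_db = snr_db)
}

# cohort config scaled for waveform simulation in tests
quick_cohort_config <- function(record_duration_s = 3e-3, window_s = 1e-3,
                                ...) {
  cohort_config(record_duration_s = record_duration_s, window_s = window_s,
                ...)
}

# a record made of an arbitrary waveform
make_record <- function(samples, fs, duration = length(samples) / fs) {
  r <- synthesize_pulse(quick_spec(record_duration_s = 8e-6), 8e-6)
  r$samples <- samples
  r$sampling_rate_hz <- fs
  r$duration_s <- duration
  r
}

# brute-force AUC: concordant-pair fraction with half credit for ties
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
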