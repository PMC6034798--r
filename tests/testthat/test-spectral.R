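test_that("least squares is exact on a single sinusoid", {
  fs <- 12.5e6
  f <- 1e6
  n <- 1250 # exactly 100 periods
  t <- (0:(n - 1)) / fs
  x <- make_record(3.2 * sin(2 * pi * f * t + 0.7), fs)
  est <- lsm_decompose(x, f)
  expect_equal(est$amplitude, 3.2, tolerance = 1e-9)
  expect_equal(est$phase_rad, 0.7, tolerance = 1e-9)
  expect_lt(residual_rms(est), 1e-9 * sqrt(mean(x$samples^2)))
})

test_that("all ten components of a noiseless pulse are recovered", {
  spec <- quick_spec(amplitudes = seq(30, 120, by = 10))
  tx <- synthesize_pulse(spec)
  med <- quick_medium()
  rx <- propagate(tx, spec, med)
  est <- lsm_decompose(rx, spec$frequencies_hz)
  truth_amp <- spec$amplitudes * component_gains(med, spec$frequencies_hz)
  expect_equal(est$amplitude, truth_amp, tolerance = 1e-6)
  truth_phase <- acgtools:::wrap_phase(
    -2 * pi * spec$frequencies_hz * component_delays(med, spec$frequencies_hz)
  )
  expect_equal(acgtools:::wrap_phase(est$phase_rad - truth_phase),
               rep(0, 10), tolerance = 1e-6)
  expect_lt(residual_rms(est), 1e-9 * sqrt(mean(rx$samples^2)))
})

test_that("streaming accumulation matches a single-chunk solve", {
  spec <- quick_spec()
  rec <- synthesize_pulse(spec)
  one <- lsm_decompose(rec, spec$frequencies_hz, chunk_size = 1e7)
  many <- lsm_decompose(rec, spec$frequencies_hz, chunk_size = 4096)
  expect_equal(one$amplitude, many$amplitude, tolerance = 1e-12)
  expect_equal(one$phase_rad, many$phase_rad, tolerance = 1e-12)
})

test_that("decomposition validates its design", {
  spec <- quick_spec()
  rec <- synthesize_pulse(spec)
  expect_error(lsm_decompose(rec, c(1e6, 1e6)), "rank-deficient")
  expect_error(lsm_decompose(rec, 7e6), "Nyquist")
  short <- make_record(rnorm(8), 12.5e6)
  expect_error(lsm_decompose(short, c(1e6, 1.2e6, 1.4e6)), "too short")
})

test_that("windowing splits records as the device does", {
  spec <- quick_spec(record_duration_s = 3e-3)
  rec <- synthesize_pulse(spec)
  wins <- window_signal(rec, 1e-3)
  expect_length(wins, 3)
  expect_equal(wins[[2]]$start_index, length(wins[[1]]$samples))
  one <- window_signal(rec, 3e-3)
  expect_length(one, 1)
  expect_equal(one[[1]]$samples, rec$samples)
  expect_error(window_signal(rec, 4e-3), "exceeds")
  # 3.5 windows fit -> trailing partial discarded
  expect_length(window_signal(rec, 0.85e-3), 3)
})

test_that("phase precision at 20 dB SNR is better than one degree", {
  spec <- quick_spec(record_duration_s = 1e-3)
  tx <- synthesize_pulse(spec)
  p_sig <- mean(tx$samples^2)
  sigma <- sqrt(p_sig / 100) # 20 dB
  n <- length(tx$samples)
  phases <- withr::with_seed(7, {
    sapply(seq_len(100), function(i) {
      noisy <- make_record(tx$samples + rnorm(n, sd = sigma),
                           spec$sampling_rate_hz)
      lsm_decompose(noisy, spec$frequencies_hz)$phase_rad
    })
  })
  se_deg <- apply(phases, 1, sd) * 180 / pi
  expect_true(all(se_deg < 1))
  # consistent with the white-noise phase-error formula
  predicted_rad <- sigma * sqrt(2 / n) / 128
  expect_equal(mean(se_deg) * pi / 180, predicted_rad, tolerance = 0.3)
  # and the formula inverts: injecting that sigma targets that SE
  expect_equal(noise_sigma_for_phase_se(128, n, predicted_rad), sigma,
               tolerance = 1e-9)
})

test_that("coarse delay finds pure delays and respects the search window", {
  spec <- quick_spec()
  tx <- synthesize_pulse(spec)
  delay <- 100e-6
  med <- medium_model(0.15, 0.15 / delay)
  rx <- propagate(tx, spec, med)
  # correlation fallback: one-sample resolution
  est_corr <- estimate_coarse_delay(rx, tx)
  expect_lt(abs(est_corr - delay), 1 / spec$sampling_rate_hz + 1e-12)
  # phase-profile path: far better than a sample
  est_phase <- estimate_coarse_delay(rx, tx,
                                     frequencies_hz = spec$frequencies_hz)
  expect_lt(abs(est_phase - delay), 1e-12)
  # zero delay
  z <- estimate_coarse_delay(tx, tx, search_window_s = c(-5e-6, 5e-6),
                             frequencies_hz = spec$frequencies_hz)
  expect_equal(z, 0, tolerance = 1e-12)
  expect_error(estimate_coarse_delay(tx, tx, search_window_s = c(1, 0)),
               "increasing")
})

test_that("coarse delay survives heavy noise", {
  spec <- quick_spec(record_duration_s = 1e-3)
  tx <- synthesize_pulse(spec)
  p_sig <- mean(tx$samples^2)
  sigma <- sqrt(p_sig) # 0 dB SNR
  n <- length(tx$samples)
  delay <- 97.4e-6
  med <- medium_model(0.15, 0.15 / delay)
  rx0 <- propagate(tx, spec, med)
  half_cycle <- 0.5 / spec$frequencies_hz[1]
  hits <- withr::with_seed(13, {
    sapply(seq_len(120), function(i) {
      noisy <- make_record(rx0$samples + rnorm(n, sd = sigma),
                           spec$sampling_rate_hz)
      est <- estimate_coarse_delay(noisy, tx,
                                   frequencies_hz = spec$frequencies_hz)
      abs(est - delay) < half_cycle
    })
  })
  expect_gte(mean(hits), 0.97)
})

test_that("least squares equals the DFT on integer-period windows", {
  spec <- quick_spec(record_duration_s = 90e-6,
                     amplitudes = seq(20, 110, by = 10))
  rec <- synthesize_pulse(spec)
  n <- length(rec$samples)
  est <- lsm_decompose(rec, spec$frequencies_hz)
  X <- stats::fft(rec$samples)
  bins <- round(spec$frequencies_hz * n / spec$sampling_rate_hz) + 1
  # each component sits exactly on a bin: amplitude 2|X_k|/n
  expect_equal(est$amplitude, 2 * Mod(X[bins]) / n, tolerance = 1e-9)
  # phase convention: sin(2 pi f t + phi) -> fft bin arg = phi - pi/2
  expect_equal(acgtools:::wrap_phase(est$phase_rad - pi / 2 - Arg(X[bins])),
               rep(0, 10), tolerance = 1e-9)
})
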