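test_that("time of flight recovers pure and dispersive delays exactly", {
  spec <- quick_spec()
  tx <- synthesize_pulse(spec)
  tx_est <- lsm_decompose(tx, spec$frequencies_hz)

  # pure delay at the published time-of-flight scale
  delay <- 97.7e-6
  med <- medium_model(0.15, 0.15 / delay)
  rx_est <- lsm_decompose(propagate(tx, spec, med), spec$frequencies_hz)
  tof <- time_of_flight(tx_est, rx_est, delay + 3e-8)
  expect_equal(tof$toa_us, rep(97.7, 10), tolerance = 1e-9) # <= 1e-3 ns

  # zero delay, identical estimates
  tof0 <- time_of_flight(tx_est, tx_est, 0)
  expect_equal(tof0$toa_us, rep(0, 10))

  # dispersive: higher frequencies faster -> strictly decreasing ToA
  med_d <- quick_medium(slope = 5, alpha0 = 0)
  rx_d <- lsm_decompose(propagate(tx, spec, med_d), spec$frequencies_hz)
  coarse <- estimate_coarse_delay(propagate(tx, spec, med_d), tx,
                                  frequencies_hz = spec$frequencies_hz)
  tof_d <- time_of_flight(tx_est, rx_d, coarse)
  truth_us <- component_delays(med_d, spec$frequencies_hz) * 1e6
  expect_true(all(diff(tof_d$toa_us) < 0))
  expect_equal(tof_d$toa_us, truth_us, tolerance = 1e-9)
})

test_that("inconsistent coarse delay raises an ambiguity error", {
  spec <- quick_spec()
  tx <- synthesize_pulse(spec)
  tx_est <- lsm_decompose(tx, spec$frequencies_hz)
  delay <- 97.7e-6
  med <- medium_model(0.15, 0.15 / delay)
  rx_est <- lsm_decompose(propagate(tx, spec, med), spec$frequencies_hz)
  # offset of 0.45 cycles of the lowest component
  bad_coarse <- delay + 0.45 / spec$frequencies_hz[1]
  expect_error(time_of_flight(tx_est, rx_est, bad_coarse),
               "ambiguity-resolution")
})

test_that("attenuation follows the fractional-loss convention", {
  spec <- quick_spec()
  tx <- synthesize_pulse(spec)
  tx_est <- lsm_decompose(tx, spec$frequencies_hz)
  expect_equal(attenuation(tx_est, tx_est)$att, rep(0, 10))

  med <- quick_medium(slope = 0, alpha0 = 1.5, gamma = 1.8)
  rx_est <- lsm_decompose(propagate(tx, spec, med), spec$frequencies_hz)
  att <- attenuation(tx_est, rx_est)
  expect_equal(att$att, 1 - component_gains(med, spec$frequencies_hz),
               tolerance = 1e-9)
  expect_true(all(diff(att$att) >= 0)) # gamma > 0: non-decreasing in f

  zero_amp <- tx_est
  zero_amp$amplitude[3] <- 0
  expect_error(attenuation(zero_amp, rx_est), "zero transmit amplitude")
})

test_that("derived acoustics reproduce the printed brain-tissue numbers", {
  d <- derived_acoustics(rep(97.4026, 10), path_length_m = 0.15)
  expect_equal(d$c_band_mps, 1540, tolerance = 1e-4)
  expect_equal(d$k_pa, 1040 * d$c_band_mps^2)
  expect_equal(signif(d$k_pa, 4), 2.466e9)

  # dc = 1.25 m/s at c ~ 1540 m/s -> |d rho / rho| = 1.6e-3 (2 sf)
  d2 <- derived_acoustics(rep(97.4026, 10), 0.15, dc_mps = 1.25)
  expect_equal(signif(abs(d2$delta_rho_rel), 2), 1.6e-3)
  d3 <- derived_acoustics(rep(97.4026, 10), 0.15, dc_mps = 0)
  expect_equal(d3$delta_rho_rel, 0)
  expect_error(derived_acoustics(c(1, -1), 0.15), "non-positive")
})

test_that("FFT features locate energy and satisfy Parseval", {
  spec <- quick_spec()
  f <- spec$frequencies_hz
  fs <- spec$sampling_rate_hz
  t <- (0:24999) / fs
  single <- make_record(5 * sin(2 * pi * f[5] * t), fs)
  ft <- fft_features(single, f)
  expect_equal(ft$spectral_centroid_hz, f[5], tolerance = 1e-3 * f[5])
  expect_gt(ft$band_energy$energy[5], 0.99 * 5^2 / 2)
  expect_lt(max(ft$band_energy$energy[-5]), 1e-3 * ft$band_energy$energy[5])

  rec <- synthesize_pulse(spec) # equal amplitudes
  ft2 <- fft_features(rec, f)
  expect_equal(ft2$spectral_centroid_hz, mean(f), tolerance = 1e-3 * mean(f))
  # Parseval: in-band energies never exceed the total, and nearly equal it
  expect_lte(sum(ft2$band_energy$energy), ft2$total_energy * (1 + 1e-12))
  expect_equal(sum(ft2$band_energy$energy), ft2$total_energy,
               tolerance = 1e-3)
})

test_that("exam aggregation takes the median over all windows and records", {
  base <- tidyr::expand_grid(record_idx = 1:3, window_idx = 1:3)
  base$a <- c(1, 2, 100, 4, 5, 6, 7, 8, 9)
  base$b <- rev(base$a)
  agg <- aggregate_exam(base)
  expect_equal(agg$a, median(base$a))
  expect_equal(agg$b, median(base$b))
  # equals brute-force median of the 9 and is permutation invariant
  shuffled <- base[sample(9), ]
  expect_equal(aggregate_exam(shuffled), agg)
  # mean mode
  expect_equal(aggregate_exam(base, method = "mean")$a, mean(base$a))
  # identical windows: aggregate equals any window
  same <- base
  same$a <- 7
  same$b <- 7
  expect_equal(aggregate_exam(same)$a, 7)
  # fewer than three records is not an exam
  expect_error(aggregate_exam(base[base$record_idx < 3, ]), "3 records")
})

test_that("robust aggregation shields features from one bad window", {
  base <- tidyr::expand_grid(record_idx = 1:3, window_idx = 1)
  base$x <- c(1, 2, 100)
  expect_equal(aggregate_exam(base)$x, 2)
})
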